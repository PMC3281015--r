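# Sliding-window conservation-ratio tracks along the genome.
#
# For features (eQTLs of one panel, or SNPs) carrying a conserved/not flag,
# the track reports per window the observed number of conserved features
# against the count expected from the genome-wide conservation fraction:
#   ratio = n_conserved / (n_features * global_fraction).

#' Sliding-window conservation-ratio track
#'
#' Windows are half-open `[start, start + window_mb)`, stepped by `step_mb`
#' within each chromosome; windows overhanging the chromosome end are kept
#' (flagged `truncated`). The global conservation fraction is computed once
#' over all features genome-wide; windows with no features (expected count 0)
#' get a missing ratio.
#'
#' @param features `data.frame` with columns `chr`, `pos_mb`, `conserved`
#'   (logical).
#' @param window_mb Window width in Mb (default 50).
#' @param step_mb Step between window starts in Mb (default 5).
#' @param chrom_lengths_mb Named numeric vector of chromosome lengths in Mb;
#'   defaults to `max(pos) + step` per chromosome present in `features`.
#' @return Object of class `conservation_track`: a `data.frame` with columns
#'   `chr`, `start_mb`, `end_mb`, `n_features`, `n_conserved`, `expected`,
#'   `ratio`, `truncated`; attribute `global_fraction`.
#' @export
sliding_conservation_ratio <- function(features, window_mb = 50, step_mb = 5,
                                       chrom_lengths_mb = NULL) {
  stopifnot(window_mb > 0, step_mb > 0)
  if (!nrow(features)) stop("no features supplied")
  stopifnot(all(c("chr", "pos_mb", "conserved") %in% names(features)))
  features$chr <- as.character(features$chr)
  global_fraction <- mean(features$conserved)
  if (is.null(chrom_lengths_mb)) {
    chrs <- chrom_levels(features$chr)
    chrom_lengths_mb <- vapply(chrs, function(ch) {
      max(features$pos_mb[features$chr == ch]) + step_mb
    }, numeric(1))
  } else {
    chrs <- chrom_levels(names(chrom_lengths_mb))
  }
  rows <- lapply(chrs, function(ch) {
    len <- chrom_lengths_mb[[ch]]
    if (is.null(len) || is.na(len)) {
      len <- max(features$pos_mb[features$chr == ch]) + step_mb
    }
    starts <- seq(0, max(0, len - step_mb), by = step_mb)
    pos <- features$pos_mb[features$chr == ch]
    cons <- features$conserved[features$chr == ch]
    do.call(rbind, lapply(starts, function(s) {
      inside <- pos >= s & pos < s + window_mb
      data.frame(chr = ch, start_mb = s, end_mb = s + window_mb,
                 n_features = sum(inside), n_conserved = sum(cons[inside]),
                 truncated = s + window_mb > len,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$expected <- out$n_features * global_fraction
  out$ratio <- ifelse(out$expected > 0, out$n_conserved / out$expected, NA_real_)
  out <- out[, c("chr", "start_mb", "end_mb", "n_features", "n_conserved",
                 "expected", "ratio", "truncated")]
  rownames(out) <- NULL
  attr(out, "global_fraction") <- global_fraction
  class(out) <- c("conservation_track", class(out))
  out
}

#' Correlation between two conservation-ratio tracks
#'
#' Pearson correlation of the window ratios over windows (matched by
#' chromosome and start) that are non-missing in both tracks. At least 3
#' shared windows are required; a track that is constant over the shared
#' windows yields a missing correlation.
#'
#' @param track1,track2 Tracks from [sliding_conservation_ratio()] (e.g. the
#'   eQTL and SNP tracks of a cross-panel comparison).
#' @return Pearson r, or NA when undefined.
#' @export
track_correlation <- function(track1, track2) {
  key1 <- paste(track1$chr, track1$start_mb)
  key2 <- paste(track2$chr, track2$start_mb)
  shared <- intersect(key1, key2)
  r1 <- track1$ratio[match(shared, key1)]
  r2 <- track2$ratio[match(shared, key2)]
  keep <- !is.na(r1) & !is.na(r2)
  if (sum(keep) < 3) stop("fewer than 3 shared non-missing windows")
  if (stats::sd(r1[keep]) == 0 || stats::sd(r2[keep]) == 0) return(NA_real_)
  stats::cor(r1[keep], r2[keep])
}

#' Plot a conservation-ratio track
#'
#' Minimal base-graphics rendering: one panel per chromosome row of window
#' midpoints against ratios, reference line at 1.
#'
#' @param x A `conservation_track`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.conservation_track <- function(x, ...) {
  chrs <- unique(x$chr)
  old <- graphics::par(mfrow = c(ceiling(length(chrs) / 4), min(4, length(chrs))),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chrs) {
    sub <- x[x$chr == ch, ]
    graphics::plot((sub$start_mb + sub$end_mb) / 2, sub$ratio, type = "l",
                   xlab = "Mb", ylab = "conservation ratio",
                   main = paste("chr", ch), ...)
    graphics::abline(h = 1, lty = 2, col = "grey")
  }
  invisible(x)
}
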