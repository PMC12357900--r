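# Quantification procedures for flow-cytometry, imaging and ChIP-derived
# tables: MFI normalization, z-score fingerprints, N:C ratio summaries,
# TSS-window peak-score aggregation, and ROUT outlier removal.

#' Normalized median fluorescence intensity
#'
#' Median MFI of a stained sample divided by the median of its matched
#' unstained control.
#'
#' @param stained,unstained Numeric vectors of per-cell intensities, or
#'   tibbles with a `value` column.
#' @return Single normalized median MFI.
#' @examples
#' normalize_mfi(c(4800, 5000, 5200), c(240, 250, 260))
#' @export
normalize_mfi <- function(stained, unstained) {
  s <- .values(stained); u <- .values(unstained)
  if (!length(s) || !length(u)) stop("empty sample", call. = FALSE)
  mu <- stats::median(u)
  if (mu <= 0) {
    stop("unstained median must be positive (got ", mu, ")", call. = FALSE)
  }
  stats::median(s) / mu
}

#' Median-MFI fold change between two conditions
#'
#' @param condition,control Numeric vectors or tibbles with `value`, measured
#'   and normalized identically.
#' @return Fold change median(condition) / median(control).
#' @export
mfi_fold_change <- function(condition, control) {
  a <- .values(condition); b <- .values(control)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  mb <- stats::median(b)
  if (mb <= 0) {
    stop("control median must be positive (got ", mb, ")", call. = FALSE)
  }
  stats::median(a) / mb
}

#' Z-score fingerprint of a paired-marker flow dataset
#'
#' Standardizes per-cell intensities on the log10 scale against a pooled
#' reference (z = (log10 value - reference mean) / reference sd, per marker),
#' then estimates a 2D kernel density of the paired z-scores on a fixed grid.
#' Multiplying all values (samples and reference) by a common positive
#' constant leaves the fingerprint unchanged.
#'
#' @param data Tidy tibble with columns `sample`, `cell_id`, `marker`,
#'   `value` (> 0), containing at least the two markers of `markers`.
#' @param markers Length-2 character vector: x and y marker.
#' @param reference Optional tibble of the same shape used for
#'   standardization; defaults to `data` pooled across samples.
#' @param grid_n Density grid resolution per axis (default 200).
#' @param grid_range Z range covered by the grid (default c(-4, 4)).
#' @param bandwidth Optional kernel bandwidth (length 2); default Scott's
#'   rule via [MASS::kde2d()]'s normal reference.
#' @param contour_mass Probability masses enclosed by the reported contour
#'   levels (default `c(0.25, 0.5, 0.75, 0.95)`).
#' @return Object of class `nfkb_fingerprint`: list with `z` (tibble:
#'   sample, cell_id, zx, zy), `density` (tibble: x, y, density; integrates
#'   to 1), `contour_levels`, `medians` (per-sample median z per marker),
#'   `markers`.
#' @export
zscore_fingerprint <- function(data, markers, reference = NULL, grid_n = 200,
                               grid_range = c(-4, 4), bandwidth = NULL,
                               contour_mass = c(0.25, 0.5, 0.75, 0.95)) {
  stopifnot(length(markers) == 2)
  need <- c("sample", "cell_id", "marker", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(reference)) reference <- data
  if (any(data$value <= 0) || any(reference$value <= 0)) {
    stop("intensities must be positive for log10 standardization",
         call. = FALSE)
  }
  ref_stats <- reference |>
    dplyr::filter(.data$marker %in% markers) |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(m = mean(log10(.data$value)),
                     s = stats::sd(log10(.data$value)), .groups = "drop")
  if (nrow(ref_stats) < 2) {
    stop("reference must contain both markers", call. = FALSE)
  }
  if (any(ref_stats$s <= 0 | !is.finite(ref_stats$s))) {
    stop("zero reference variance for marker ",
         paste(ref_stats$marker[!is.finite(ref_stats$s) | ref_stats$s <= 0],
               collapse = ", "), call. = FALSE)
  }
  zed <- data |>
    dplyr::filter(.data$marker %in% markers) |>
    dplyr::left_join(ref_stats, by = "marker") |>
    dplyr::mutate(z = (log10(.data$value) - .data$m) / .data$s) |>
    dplyr::select("sample", "cell_id", "marker", "z") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "z")
  z <- dplyr::rename(zed, zx = dplyr::all_of(markers[1]),
                     zy = dplyr::all_of(markers[2])) |>
    tidyr::drop_na()
  kde <- if (is.null(bandwidth)) {
    MASS::kde2d(z$zx, z$zy, n = grid_n, lims = c(grid_range, grid_range))
  } else {
    MASS::kde2d(z$zx, z$zy, h = bandwidth, n = grid_n,
                lims = c(grid_range, grid_range))
  }
  dx <- diff(kde$x[1:2]); dy <- diff(kde$y[1:2])
  dens <- kde$z / (sum(kde$z) * dx * dy)   # renormalize on the grid
  # density level enclosing each requested probability mass
  ord <- sort(as.vector(dens), decreasing = TRUE)
  cum <- cumsum(ord * dx * dy)
  levels <- vapply(contour_mass, function(p) ord[which.min(abs(cum - p))],
                   numeric(1))
  medians <- z |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(zx = stats::median(.data$zx),
                     zy = stats::median(.data$zy), .groups = "drop") |>
    tidyr::pivot_longer(c("zx", "zy"), names_to = "axis",
                        values_to = "median_z") |>
    dplyr::mutate(marker = ifelse(.data$axis == "zx", markers[1],
                                  markers[2])) |>
    dplyr::select("sample", "marker", "median_z")
  structure(
    list(z = z,
         density = tibble::tibble(x = rep(kde$x, times = length(kde$y)),
                                  y = rep(kde$y, each = length(kde$x)),
                                  density = as.vector(dens)),
         contour_levels = stats::setNames(levels, paste0("p", contour_mass)),
         medians = medians,
         markers = markers),
    class = "nfkb_fingerprint")
}

#' @export
print.nfkb_fingerprint <- function(x, ...) {
  cat("<nfkb_fingerprint>", x$markers[1], "vs", x$markers[2], "-",
      nrow(x$z), "cells,", dplyr::n_distinct(x$z$sample), "sample(s)\n")
  invisible(x)
}

#' Per-sample summary of nuclear:cytoplasmic ratios
#'
#' Rows with non-positive ratios are rejected (with a message reporting the
#' count); an error is raised if nothing survives.
#'
#' @param table Tibble with columns `sample` and `ratio` (one row per cell).
#' @param probs Quantiles reported for violin-style plotting.
#' @return Tibble: `sample`, `n`, `n_rejected`, `mean`, `sd`, `median`, and
#'   one `q<p>` column per requested quantile.
#' @export
nc_ratio_summary <- function(table, probs = c(0.25, 0.5, 0.75)) {
  stopifnot(all(c("sample", "ratio") %in% names(table)))
  bad <- !is.finite(table$ratio) | table$ratio <= 0
  if (any(bad)) {
    message("nc_ratio_summary: rejected ", sum(bad),
            " non-positive/invalid ratio row(s)")
  }
  rejected <- table[bad, , drop = FALSE] |>
    dplyr::count(.data$sample, name = "n_rejected")
  kept <- table[!bad, , drop = FALSE]
  if (!nrow(kept)) stop("no valid (positive) ratios", call. = FALSE)
  stats_tbl <- kept |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$ratio),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$ratio), 0),
      median = stats::median(.data$ratio),
      .groups = "drop")
  quant_tbl <- kept |>
    dplyr::group_by(.data$sample) |>
    dplyr::reframe(prob = probs,
                   q = stats::quantile(.data$ratio, probs, names = FALSE)) |>
    dplyr::mutate(name = sprintf("q%02d", round(100 * .data$prob))) |>
    dplyr::select("sample", "name", "q") |>
    tidyr::pivot_wider(names_from = "name", values_from = "q")
  stats_tbl |>
    dplyr::left_join(quant_tbl, by = "sample") |>
    dplyr::left_join(rejected, by = "sample") |>
    dplyr::mutate(n_rejected = dplyr::coalesce(.data$n_rejected, 0L))
}

#' Peak scores within a window around a transcription start site
#'
#' 0-based half-open intervals: a peak `[start, end)` is in-window iff it
#' overlaps `[position - half_window, position + half_window + 1)`. The
#' window is symmetric; strand is ignored.
#'
#' @param peaks Tibble with columns `chrom`, `start`, `end`, `score`, and
#'   optionally `subunit`, `dataset`.
#' @param tss One-row tibble (or list) with `gene`, `chrom`, `position`.
#' @param half_window Half-width in bp (> 0, default 1000).
#' @return Tibble of in-window peaks with a `gene` column, grouped-friendly
#'   (retains `subunit` when present).
#' @export
tss_window_scores <- function(peaks, tss, half_window = 1000) {
  stopifnot(half_window > 0)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(peaks)))
  if (is.data.frame(tss)) {
    stopifnot(nrow(tss) == 1)
    tss <- as.list(tss)
  }
  if (any(peaks$start >= peaks$end)) {
    stop("peaks must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  win_lo <- tss$position - half_window
  win_hi <- tss$position + half_window + 1   # half-open upper bound
  hit <- peaks$chrom == tss$chrom & peaks$start < win_hi & peaks$end > win_lo
  out <- peaks[hit, , drop = FALSE]
  out$gene <- tss$gene
  tibble::as_tibble(out)
}

#' ROUT-style robust outlier removal (constant model)
#'
#' Robust location by iteratively reweighted least squares (Lorentzian
#' weights), robust scale (RSDR) from the 68.27th percentile of absolute
#' residuals with the n/(n-1) small-sample correction, two-tailed t-based
#' p-value per point, and false-discovery-rate removal at rate `q` working
#' from the most extreme point inward. Deterministic; identical values yield
#' no outliers.
#'
#' @param values Numeric vector, length >= 3.
#' @param q FDR rate in (0, 0.3]; the conventional setting is 0.01 (1%).
#' @return List with `kept`, `outliers`, `is_outlier` (logical, input
#'   order), `center`, `rsdr`.
#' @examples
#' rout_outliers(c(1, 1.2, 0.9, 1.1, 100))$outliers
#' @export
rout_outliers <- function(values, q = 0.01) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 finite values", call. = FALSE)
  if (q <= 0 || q > 0.3) stop("q must lie in (0, 0.3]", call. = FALSE)

  center <- stats::median(values)
  s <- stats::quantile(abs(values - center), 0.6827, names = FALSE)
  if (s <= 0) s <- stats::mad(values)
  if (s > 0) {
    for (iter in 1:100) {   # IRLS, Lorentzian weights
      w <- 1 / (1 + ((values - center) / s)^2)
      new_center <- sum(w * values) / sum(w)
      s_new <- stats::quantile(abs(values - new_center), 0.6827,
                               names = FALSE)
      done <- abs(new_center - center) < 1e-12 * max(1, abs(center))
      center <- new_center
      if (s_new > 0) s <- s_new
      if (done) break
    }
  }
  res <- values - center
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr <= 0) {
    # degenerate bulk: any point off the consensus value is an outlier
    is_out <- res != 0
    return(list(kept = values[!is_out], outliers = values[is_out],
                is_outlier = is_out, center = center, rsdr = 0))
  }
  p <- 2 * stats::pt(abs(res) / rsdr, df = n - 1, lower.tail = FALSE)
  ord <- order(p)
  thresh <- q * seq_len(n) / n
  passed <- p[ord] <= thresh
  k <- if (any(passed)) max(which(passed)) else 0
  is_out <- logical(n)
  if (k > 0) is_out[ord[seq_len(k)]] <- TRUE
  list(kept = values[!is_out], outliers = values[is_out],
       is_outlier = is_out, center = center, rsdr = rsdr)
}
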