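#' G1 peak position of a flow-cytometry sample
#'
#' Mode-finding summary feeding the ploidy classifier: a Gaussian-kernel
#' density (Silverman's rule bandwidth) is fitted to the fluorescence
#' events and the lowest-fluorescence local mode whose density exceeds 10%
#' of the global maximum is returned.  In an asynchronous culture this is
#' the G1 peak; the G2 peak sits at twice its position.
#'
#' @param sample A `flow_sample` (see [generate_flow_sample()]) or numeric
#'   vector of fluorescence events; at least 1000 events.
#' @return Fluorescence position of the G1 peak.
#' @export
g1_peak <- function(sample) {
  events <- if (inherits(sample, "flow_sample")) sample$events else sample
  if (length(events) < 1000L) stop("need at least 1000 events")
  d <- density(events, bw = "nrd0")
  y <- d$y
  is_mode <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  qualifying <- which(is_mode & y >= 0.1 * max(y))
  if (!length(qualifying)) stop("no qualifying mode")
  d$x[qualifying[1L]]
}

#' Call colony ploidy by exact one-dimensional k-means (k = 2)
#'
#' Clusters per-colony G1-peak positions into two groups.  In one
#' dimension the optimal k-means partition is a threshold split of the
#' sorted values, so all `n - 1` splits are enumerated and the
#' within-cluster sum of squares (WSS) minimised exactly -- no
#' initialisation sensitivity.  The cluster with the lower centroid is
#' labelled haploid (cluster positions correspond to genome size).  With
#' `anchors` supplied, each colony is instead assigned to the nearer of
#' the haploid/diploid reference positions (needed when only one colony is
#' available).
#'
#' @param peaks Named numeric vector: colony_id -> G1-peak position.
#' @param anchors Optional `c(haploid_ref, diploid_ref)` control-sample
#'   positions.
#' @return List of class `ploidy_calls`: `assignments` (named integer
#'   vector of 1/2), `centers` (cluster means, haploid first), `wss_k1`
#'   (total sum of squares, the k = 1 objective), `wss_k2` (optimal k = 2
#'   objective).
#' @export
call_ploidy <- function(peaks, anchors = NULL) {
  if (is.null(names(peaks)) || any(!nzchar(names(peaks)))) {
    stop("peaks must be named by colony")
  }
  if (!is.null(anchors)) {
    if (length(anchors) != 2L || anchors[1L] >= anchors[2L]) {
      stop("anchors must be c(haploid_ref, diploid_ref) with haploid < diploid")
    }
    assign <- ifelse(abs(peaks - anchors[1L]) <= abs(peaks - anchors[2L]),
                     1L, 2L)
    names(assign) <- names(peaks)
    centers <- c(
      if (any(assign == 1L)) mean(peaks[assign == 1L]) else anchors[1L],
      if (any(assign == 2L)) mean(peaks[assign == 2L]) else anchors[2L]
    )
    wss2 <- sum((peaks - centers[assign])^2)
    return(.ploidy_calls(assign, centers, peaks, wss2))
  }
  if (length(peaks) < 2L) stop("need >= 2 colonies (or anchors)")
  if (diff(range(peaks)) == 0) stop("no separation")
  ord <- order(peaks)
  sorted <- peaks[ord]
  n <- length(sorted)
  best <- NULL
  best_wss <- Inf
  for (k in seq_len(n - 1L)) {
    lo <- sorted[seq_len(k)]
    hi <- sorted[(k + 1L):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best_wss) {
      best_wss <- wss
      best <- k
    }
  }
  assign_sorted <- rep(c(1L, 2L), c(best, n - best))
  assign <- integer(n)
  assign[ord] <- assign_sorted
  names(assign) <- names(peaks)
  centers <- c(mean(sorted[seq_len(best)]), mean(sorted[(best + 1L):n]))
  .ploidy_calls(assign, centers, peaks, best_wss)
}

.ploidy_calls <- function(assign, centers, peaks, wss2) {
  structure(
    list(
      assignments = assign,
      centers = centers,
      wss_k1 = sum((peaks - mean(peaks))^2),
      wss_k2 = wss2
    ),
    class = "ploidy_calls"
  )
}

#' Diploid fraction of a hydroxyurea-arrested sample
#'
#' Arrest collapses each ploidy onto its G1 peak (haploids at `c`,
#' diploids at `2c`), so a gate at `1.5 * haploid_peak` -- midway between
#' the peaks -- separates the ploidies, except for the fraction of cells
#' that escape arrest and remain at G2.  Escaped haploids (at `2c`) and
#' escaped diploids (at `4c`) both land above the gate, so the raw
#' above-gate fraction satisfies `raw = d + (1 - d) * esc` for true
#' diploid fraction `d`; the returned estimate inverts this:
#' `d = (raw - esc) / (1 - esc)`, clipped to `[0, 1]`.
#'
#' @param sample Arrested `flow_sample` or numeric event vector.
#' @param haploid_peak Haploid G1 position `c` (> 0).
#' @param escape_fraction Assumed arrest-escape fraction (default 0.10).
#' @return Estimated diploid fraction in `[0, 1]`.
#' @export
diploid_fraction <- function(sample, haploid_peak, escape_fraction = 0.10) {
  events <- if (inherits(sample, "flow_sample")) {
    if (!isTRUE(sample$arrested)) stop("sample is not hydroxyurea-arrested")
    sample$events
  } else {
    sample
  }
  if (haploid_peak <= 0) stop("haploid_peak must be > 0")
  if (escape_fraction < 0 || escape_fraction >= 1) {
    stop("escape_fraction must lie in [0, 1)")
  }
  gate <- 1.5 * haploid_peak
  if (gate <= min(events) || gate >= max(events)) {
    # all events on one side: the gate carries no information unless the
    # sample is genuinely pure, which a one-sided sample is
    if (gate >= max(events)) {
      raw <- 0
    } else {
      raw <- 1
    }
  } else {
    raw <- mean(events > gate)
  }
  min(max((raw - escape_fraction) / (1 - escape_fraction), 0), 1)
}

#' Change in diploid frequency between two time points
#'
#' @param day0 Initial diploid fraction in `[0, 1]`.
#' @param day14 Final diploid fraction in `[0, 1]`.
#' @return `day14 - day0`.
#' @export
frequency_change <- function(day0, day14) {
  stopifnot(day0 >= 0, day0 <= 1, day14 >= 0, day14 <= 1)
  day14 - day0
}

#' Per-chromosome coverage ratios and aneuploidy flags
#'
#' For each chromosome, the proportion of sequenced sites relative to the
#' proportion of mappable sites in the reference:
#' `ratio_c = (count_c / sum(count)) / (ref_c / sum(ref))`.
#' Euploid chromosomes sit near 1.0; a whole-chromosome gain shifts
#' coverage towards 2x in a haploid and 1.5x in a diploid, so chromosomes
#' with `ratio >= 1.4` or `<= 0.6` (midway between euploid and
#' single-gain expectations) are flagged.
#'
#' @param counts Named numeric vector of mapped-site counts per
#'   chromosome, >= 0.
#' @param ref Named numeric vector of reference mappable-site totals,
#'   > 0, same chromosomes.
#' @param flag_high,flag_low Flag thresholds (defaults 1.4 / 0.6).
#' @return Tibble with columns `chromosome`, `ratio`, `flagged`.
#' @export
coverage_ratios <- function(counts, ref, flag_high = 1.4, flag_low = 0.6) {
  if (is.null(names(counts)) || is.null(names(ref))) {
    stop("counts and ref must be named by chromosome")
  }
  if (!setequal(names(counts), names(ref))) {
    stop("counts and ref must cover the same chromosomes")
  }
  ref <- ref[names(counts)]
  if (any(counts < 0)) stop("negative counts")
  if (sum(ref) <= 0 || any(ref <= 0)) stop("reference totals must be positive")
  if (sum(counts) <= 0) stop("no mapped sites")
  ratio <- (counts / sum(counts)) / (ref / sum(ref))
  tibble::tibble(
    chromosome = names(counts),
    ratio = unname(ratio),
    flagged = unname(ratio >= flag_high | ratio <= flag_low)
  )
}

#' Span of ploidy polymorphism in a colony time series
#'
#' Given per-colony ploidy calls sampled across generations, reports the
#' first generation at which a diploid was sampled, the last generation at
#' which a haploid was sampled, and their difference -- the minimum number
#' of generations over which the population was polymorphic for genome
#' size.
#'
#' @param calls Data frame with columns `generation` and `ploidy` (1/2),
#'   one row per sampled colony.
#' @return List with `first_diploid`, `last_haploid`, `span`.
#' @examples
#' calls <- data.frame(generation = c(651, 744, 744, 1302, 1302, 1395),
#'                     ploidy = c(1, 1, 2, 1, 2, 2))
#' polymorphism_span(calls)$span  # 558
#' @export
polymorphism_span <- function(calls) {
  if (!all(c("generation", "ploidy") %in% names(calls))) {
    stop("need columns generation, ploidy")
  }
  if (!any(calls$ploidy == 2) || !any(calls$ploidy == 1)) {
    stop("need both ploidy levels in the series")
  }
  first_diploid <- min(calls$generation[calls$ploidy == 2])
  last_haploid <- max(calls$generation[calls$ploidy == 1])
  list(
    first_diploid = first_diploid,
    last_haploid = last_haploid,
    span = last_haploid - first_diploid
  )
}
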