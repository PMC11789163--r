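# Search statistics: generation-probability estimates, center RMSD, the
# top-20 ergodic metric, cross-search comparisons over space groups,
# percentile summaries, and landscape export.

#' Estimate a polymorph generation probability
#'
#' N_hits / denominator, where hits are records matching the target under
#' the duplicate criterion.  For a pseudo-random search the denominator is
#' the number of trials N; for EVCCP streams it is the total number of
#' generated polymorphs (steps x M) or M for a single step.
#'
#' @param records List of `polymorph_record`s (or an object with a
#'   `records` element).
#' @param target The reference `polymorph_record`.
#' @param sg The shared `space_group`.
#' @param denominator Total number of generation trials (defaults to the
#'   number of records).
#' @param tol A [duplicate_tol()] list.
#' @return Probability in [0, 1].
#' @export
estimate_probability <- function(records, target, sg,
                                 denominator = NULL, tol = duplicate_tol()) {
  if (!is.null(records$records)) records <- records$records
  if (is.null(denominator)) denominator <- length(records)
  if (denominator <= 0) stop("denominator must be positive")
  if (denominator < length(records))
    stop("denominator must be >= the number of contributing records")
  hits <- sum(vapply(records, function(r) is_duplicate(r, target, sg, tol),
                     FALSE))
  hits / denominator
}

#' Root-mean-square displacement of molecular centers
#'
#' The square root of the mean over the Z' molecules of the squared center
#' displacement between two packings; zero iff all centers coincide.
#'
#' @param X,X_ref `packing_state`s (or anything with a `com` matrix) of
#'   identical layout.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' a <- list(com = matrix(c(3, 4, 0), 1, 3))
#' b <- list(com = matrix(0, 1, 3))
#' rmsd_com(a, b)  # 5
rmsd_com <- function(X, X_ref) {
  if (!all(dim(X$com) == dim(X_ref$com)))
    stop("layouts are incompatible")
  sqrt(mean(rowSums((X$com - X_ref$com)^2)))
}

#' Mean-shifted top-20 energy metric
#'
#' Mean of the 20 lowest energies minus the mean of all energies, a
#' number-density measure of low-energy configurations (window truncated to
#' the sample size when fewer than 20 energies are available).  Always
#' non-positive.
#'
#' @param energies Numeric vector of unbiased energies.
#' @param window Window size (default 20).
#' @return kJ/mol.
#' @export
top20_gap <- function(energies, window = 20L) {
  energies <- energies[is.finite(energies)]
  if (length(energies) == 0L) stop("no finite energies")
  w <- min(window, length(energies))
  mean(sort(energies)[seq_len(w)]) - mean(energies)
}

#' Stepwise trace of the top-20 metric
#'
#' The metric recomputed on every prefix of the generation-ordered energy
#' sequence (or on prefixes at the requested evaluation points).
#'
#' @param energies Energies in generation order.
#' @param at Integer prefix lengths at which to evaluate (default: all).
#' @param window Window size.
#' @return Data frame with columns `n` and `metric`.
#' @export
metric_trace <- function(energies, at = seq_along(energies), window = 20L) {
  at <- sort(unique(as.integer(at)))
  at <- at[at >= 1 & at <= length(energies)]
  data.frame(n = at,
             metric = vapply(at, function(n)
               top20_gap(energies[seq_len(n)], window), 0))
}

#' Compare a search metric across space groups
#'
#' R_g is the fraction of groups where the replica-exchange metric is
#' strictly lower than the pseudo-random one; delta_E_g is the mean
#' difference (MRE minus PR), negative when MRE is lower on average.
#'
#' @param metric_mre,metric_pr Equal-length numeric vectors, one value per
#'   space group.
#' @return List with `R_g`, `dE_g`, and the per-group differences.
#' @export
compare_groups <- function(metric_mre, metric_pr) {
  if (length(metric_mre) != length(metric_pr))
    stop("metric vectors must have equal length")
  d <- metric_mre - metric_pr
  list(R_g = mean(metric_mre < metric_pr), dE_g = mean(d), diff = d)
}

#' Nearest-rank percentile of sorted energies
#'
#' @param energies Numeric vector.
#' @param p Percentile in percent (e.g. 0.05 for the 0.05% point).
#' @return The ceiling(p/100 * n)-th order statistic (at least the first).
#' @export
nearest_rank <- function(energies, p) {
  x <- sort(energies[is.finite(energies)])
  n <- length(x)
  if (n == 0L) stop("no finite energies")
  x[max(1L, ceiling(p / 100 * n))]
}

#' Summarize a search record collection
#'
#' Deduplicates, then reports hit counts and the composite unbiased energy
#' metrics: E_min, the top-20 window mean, the overall mean, and
#' nearest-rank percentiles.
#'
#' @param records List of `polymorph_record`s (or an object carrying
#'   `records`).
#' @param sg The shared `space_group`.
#' @param tol A [duplicate_tol()] list.
#' @param percentiles Percent points to report.
#' @param dedup If `FALSE`, records are assumed already distinct.
#' @return Object of class `search_summary`.
#' @export
summarize_search <- function(records, sg, tol = duplicate_tol(),
                             percentiles = c(0.05, 1, 5), dedup = TRUE) {
  if (!is.null(records$records)) records <- records$records
  if (length(records) == 0L) stop("no records")
  n <- length(records)
  distinct <- if (dedup) deduplicate(records, sg, tol) else records
  u <- vapply(distinct, function(r) r$U_unb, 0)
  u <- u[is.finite(u)]
  pct <- vapply(percentiles, function(p) nearest_rank(u, p), 0)
  structure(list(
    N = n, N_distinct = length(distinct), E_min = min(u),
    E_T20 = mean(sort(u)[seq_len(min(20L, length(u)))]),
    E_mean = mean(u),
    percentiles = setNames(pct, paste0(percentiles, "%"))),
    class = "search_summary")
}

#' @export
print.search_summary <- function(x, ...) {
  cat(sprintf("Search summary: N = %d, N_distinct = %d\n", x$N,
              x$N_distinct))
  cat(sprintf("  E_min = %.4f  <E>_T20 = %.4f  <E> = %.4f kJ/mol\n",
              x$E_min, x$E_T20, x$E_mean))
  cat("  percentiles:",
      paste(sprintf("%s: %.4f", names(x$percentiles), x$percentiles),
            collapse = "  "), "\n")
  invisible(x)
}

#' Energy-density landscape table
#'
#' One row per distinct polymorph: density against unbiased energy, the
#' standard landscape plot coordinates.
#'
#' @param records List of `polymorph_record`s (or an object carrying
#'   `records`).
#' @param mol,sg As in [density()].
#' @param tol A [duplicate_tol()] list.
#' @param dedup Deduplicate first?
#' @return Data frame with columns `density_g_cm3`, `energy_kj_mol`,
#'   `distinct_id`, `converged`.
#' @export
landscape_table <- function(records, mol, sg, tol = duplicate_tol(),
                            dedup = TRUE) {
  if (!is.null(records$records)) records <- records$records
  if (length(records) == 0L) stop("no records")
  distinct <- if (dedup) deduplicate(records, sg, tol) else records
  data.frame(
    density_g_cm3 = vapply(distinct,
                           function(r) crystal_density(r$state, mol, sg), 0),
    energy_kj_mol = vapply(distinct, function(r) r$U_unb, 0),
    distinct_id = seq_along(distinct),
    converged = vapply(distinct, function(r) isTRUE(r$converged), FALSE))
}

#' Landscape plot
#'
#' @param x A data frame from [landscape_table()].
#' @param ... Passed to [plot()].
#' @export
plot_landscape <- function(x, ...) {
  plot(x$density_g_cm3, x$energy_kj_mol,
       xlab = expression(paste("density (g ", cm^-3, ")")),
       ylab = "lattice energy (kJ/mol)", pch = 19, ...)
}
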