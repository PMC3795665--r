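# Vg/Vm mutation-selection test.
#
# Under neutrality in diploids the ratio of standing per-site variation in
# a natural isolate (Vg) to the per-site-per-generation mutational
# variation accumulated in bottlenecked MA lines (Vm) equals 4*Ne. An
# implied Ne orders of magnitude below an independent estimate of the
# species' Ne indicates purifying selection on the locus.

#' Per-site diversity across a pileup (Vg estimator)
#'
#' Gini-Simpson diversity per site, h_i = 1 - sum_b (count_b / depth_i)^2
#' over the five pileup alleles; the mean over covered sites estimates the
#' standing per-site variation and the SEM uses site-level dispersion
#' (SD / sqrt(n_sites)). Zero-depth sites are excluded and counted.
#'
#' @param pileup An `rdna_pileup`.
#' @param positions Optional subset of 1-based positions to evaluate
#'   (default: all).
#' @return List with `h` (per-site values, NA at zero depth), `vg` (mean),
#'   `sem`, `n_sites` (evaluated) and `n_zero_depth` (excluded).
#' @export
per_site_diversity <- function(pileup, positions = NULL) {
  stopifnot(inherits(pileup, "rdna_pileup"))
  cm <- pileup$counts
  if (!is.null(positions)) cm <- cm[positions, , drop = FALSE]
  depth <- rowSums(cm)
  h <- rep(NA_real_, nrow(cm))
  ok <- depth > 0
  h[ok] <- 1 - rowSums((cm[ok, , drop = FALSE] / depth[ok])^2)
  n <- sum(ok)
  if (!n) stop("no covered sites to evaluate", call. = FALSE)
  list(h = h,
       vg = mean(h[ok]),
       sem = sd(h[ok]) / sqrt(n),
       n_sites = n,
       n_zero_depth = sum(!ok))
}

#' Convert accumulated diversity to a per-generation rate (Vm)
#'
#' @param diversity_mean Mean per-site diversity accumulated in an MA line.
#' @param t Generations of propagation (> 0).
#' @return Per-site per-generation mutational variation.
#' @export
vm_per_generation <- function(diversity_mean, t) {
  stopifnot_scalar_num(diversity_mean, "diversity_mean")
  stopifnot_scalar_num(t, "t")
  if (t <= 0) stop("t (generations) must be > 0", call. = FALSE)
  diversity_mean / t
}

#' Vg/Vm ratio test
#'
#' Joint Vm is the unweighted arithmetic mean over MA lines, rounded to
#' `sig_figs` significant figures before the ratio (so reported ratios are
#' reproducible from the reported joint Vm); the implied effective
#' population size is ratio / 4.
#'
#' @param vg Standing per-site variation of the natural isolate.
#' @param vm_lines Per-line Vm values (all > 0).
#' @param sig_figs Significant figures for the joint Vm (default 3);
#'   `NULL` keeps it unrounded.
#' @return An `rdna_selection`: list with `vg`, `vm_lines`, `joint_vm`,
#'   `ratio`, `ne_implied`.
#' @export
vg_vm_test <- function(vg, vm_lines, sig_figs = 3L) {
  stopifnot_scalar_num(vg, "vg")
  if (!length(vm_lines) || !is.numeric(vm_lines))
    stop("vm_lines must be a non-empty numeric vector", call. = FALSE)
  if (any(vm_lines <= 0)) stop("all Vm values must be > 0", call. = FALSE)
  joint <- mean(vm_lines)
  if (!is.null(sig_figs)) joint <- signif(joint, sig_figs)
  ratio <- vg / joint
  structure(
    list(vg = vg, vm_lines = vm_lines, joint_vm = joint,
         ratio = ratio, ne_implied = ratio / 4),
    class = "rdna_selection")
}

#' @export
print.rdna_selection <- function(x, ...) {
  cat(sprintf("Vg = %.3g; joint Vm = %.3g over %d line(s)\n",
              x$vg, x$joint_vm, length(x$vm_lines)))
  cat(sprintf("Vg/Vm = %.2f  =>  implied Ne = %.1f\n", x$ratio, x$ne_implied))
  invisible(x)
}

#' Qualitative purifying-selection verdict
#'
#' Flags purifying selection when the implied Ne sits at least
#' `order_cutoff` orders of magnitude below an independent reference Ne,
#' and reports the gap in orders of magnitude.
#'
#' @param stats An `rdna_selection` from [vg_vm_test()].
#' @param reference_ne Independent effective-population-size estimate (> 0).
#' @param order_cutoff Orders-of-magnitude gap required to flag (default 2).
#' @return List with `purifying` (flag), `gap_orders` (log10 gap) and
#'   `gap_orders_rounded`.
#' @export
selection_verdict <- function(stats, reference_ne, order_cutoff = 2) {
  stopifnot(inherits(stats, "rdna_selection"))
  stopifnot_scalar_num(reference_ne, "reference_ne")
  if (reference_ne <= 0) stop("reference_ne must be > 0", call. = FALSE)
  gap <- log10(reference_ne / stats$ne_implied)
  list(purifying = gap >= order_cutoff,
       gap_orders = gap,
       gap_orders_rounded = round(gap))
}

#' JSON report of a selection test
#'
#' @param stats An `rdna_selection`.
#' @param path Output path.
#' @param verdict Optional result of [selection_verdict()] to embed.
#' @return Invisibly, `path`.
#' @export
write_selection_json <- function(stats, path, verdict = NULL) {
  stopifnot(inherits(stats, "rdna_selection"))
  x <- unclass(stats)
  if (!is.null(verdict)) x$verdict <- verdict
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
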