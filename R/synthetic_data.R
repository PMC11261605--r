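#' Noise model for synthetic ThT traces
#'
#' @param sigma Additive Gaussian standard deviation on fluorescence (a.u.,
#'   >= 0).
#' @param seed Optional integer seed; when given, generation is
#'   bit-reproducible and the caller's RNG state is untouched.
#' @param cadence Sampling interval in hours (default 5 min, the plate
#'   reader's measurement cycle).
#' @param quench Multiplier in (0, 1] on the plateau amplitude, emulating
#'   fluorescence quenching by the azobenzene moiety.
#' @return A list of class \code{"noise_spec"}.
#' @export
noise_spec <- function(sigma = 2, seed = NULL, cadence = 1 / 12, quench = 1) {
  if (sigma < 0) rlang::abort("sigma must be non-negative")
  stopifnot(cadence > 0, quench > 0, quench <= 1)
  structure(list(sigma = sigma, seed = seed, cadence = cadence,
                 quench = quench), class = "noise_spec")
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate noisy synthetic ThT traces
#'
#' Samples [model_curve()] at the noise spec's cadence over \code{duration}
#' hours (with the plateau scaled by the quench factor) and adds i.i.d.
#' Gaussian noise per replicate.
#'
#' @param p A [kinetic_params()].
#' @param n A [noise_spec()].
#' @param duration Trace length in hours (> 0).
#' @param replicates Number of replicate wells (>= 1; the assay plates three
#'   aliquots per sample).
#' @return A tibble with columns \code{time_h}, \code{fluorescence_au},
#'   \code{replicate}.
#' @export
gen_tht_trace <- function(p, n = noise_spec(), duration = 24, replicates = 3) {
  stopifnot(inherits(p, "kinetic_params"), inherits(n, "noise_spec"),
            duration > 0, replicates >= 1)
  pq <- kinetic_params(dF_pl = p$dF_pl * n$quench, lam = p$lam, kap = p$kap,
                       n_c = p$n_c, n_2 = p$n_2, baseline = p$baseline)
  times <- seq(0, duration, by = n$cadence)
  clean <- model_curve(pq, times)
  with_optional_seed(n$seed, {
    purrr::map_dfr(seq_len(replicates), function(r) {
      tibble::tibble(time_h = times,
                     fluorescence_au = clean + rnorm(length(times), 0, n$sigma),
                     replicate = r)
    })
  })
}

#' Generate a synthetic WAXS peak list from a topology
#'
#' Takes the repeats predicted by [predict_waxs_repeats()], jitters their
#' d-spacings with Gaussian noise, tags them present and assigns a common
#' Gaussian peak width; optional decoy entries are appended as absent peaks.
#'
#' @param topo A [topology()].
#' @param spec A [lattice_spec()].
#' @param width Gaussian peak width in A (> 0).
#' @param d_noise Gaussian jitter s.d. on the d-spacings (A).
#' @param seed Optional integer seed.
#' @param decoys Numeric d-spacings to append as absent entries.
#' @return A tibble with columns \code{d}, \code{width}, \code{present},
#'   \code{assignment}.
#' @export
gen_waxs_peaks <- function(topo = topology(), spec = lattice_spec(),
                           width = 0.3, d_noise = 0, seed = NULL,
                           decoys = numeric()) {
  stopifnot(width > 0, d_noise >= 0)
  peaks <- predict_waxs_repeats(topo, spec)
  with_optional_seed(seed, {
    peaks$d <- peaks$d + rnorm(nrow(peaks), 0, d_noise)
  })
  peaks$width <- width
  if (length(decoys)) {
    peaks <- dplyr::bind_rows(peaks, tibble::tibble(
      d = decoys, present = FALSE, assignment = "decoy", width = width))
  }
  dplyr::select(peaks, "d", "width", "present", "assignment")
}

#' Generate synthetic ssNMR contact observations from a lattice model
#'
#' Applies the spin-diffusion constraint logic: a residue pair is observed as
#' a cross-peak exactly when its minimum inter-strand distance in the model
#' is below the threshold, and the bound direction is assigned accordingly
#' (\code{"lt"} for an observed contact, \code{"gt"} for an absent one).
#'
#' @param m A [build_lattice()] model.
#' @param threshold Distance threshold in A (default 6, the spin-diffusion
#'   detection bound).
#' @param pairs List of residue pairs, each a length-2 vector of labels
#'   (e.g. \code{list(c("L28", "F34"))}).
#' @param scope Distance scope passed to [residue_pair_distance()].
#' @return A tibble with columns \code{a}, \code{b}, \code{distance},
#'   \code{observed}, \code{bound}, \code{threshold}.
#' @export
gen_contacts <- function(m, threshold = 6, pairs = list(c("L28", "F34")),
                         scope = "inter_strand") {
  stopifnot(inherits(m, "lattice_model"), threshold > 0, length(pairs) >= 1)
  purrr::map_dfr(pairs, function(pr) {
    d <- residue_pair_distance(m, pr[[1]], pr[[2]], scope = scope)
    tibble::tibble(a = pr[[1]], b = pr[[2]], distance = d,
                   observed = d < threshold,
                   bound = ifelse(d < threshold, "lt", "gt"),
                   threshold = threshold)
  })
}
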