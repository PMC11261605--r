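#' Bundle WAXS and ssNMR observables into a constraint set
#'
#' @param waxs Data frame with columns \code{d} (A) and \code{present}
#'   (logical); an absent entry encodes "no reflection observed near d".
#' @param contacts Data frame with columns \code{a}, \code{b} (residue
#'   labels), \code{bound} (\code{"lt"} or \code{"gt"}) and \code{threshold}
#'   (A); optional \code{scope} column (default \code{"inter_strand"}).
#' @return A list of class \code{"observable_set"}.
#' @export
observable_set <- function(waxs = NULL, contacts = NULL) {
  waxs <- if (is.null(waxs) || !nrow(tibble::as_tibble(waxs))) {
    tibble::tibble(d = numeric(), present = logical())
  } else tibble::as_tibble(waxs)
  contacts <- if (is.null(contacts) || !nrow(tibble::as_tibble(contacts))) {
    tibble::tibble(a = character(), b = character(),
                   bound = character(), threshold = numeric())
  } else tibble::as_tibble(contacts)
  if (nrow(waxs)) stopifnot(all(waxs$d > 0), is.logical(waxs$present))
  if (nrow(contacts)) {
    stopifnot(all(contacts$bound %in% c("lt", "gt")),
              all(contacts$threshold > 0))
    if (!("scope" %in% names(contacts))) contacts$scope <- "inter_strand"
  }
  structure(list(waxs = waxs, contacts = contacts), class = "observable_set")
}

#' Read a constraint set from JSON
#'
#' Expects \code{{"waxs": [{"d": 4.7, "present": true}, ...],
#' "contacts": [{"a": "L28", "b": "F34", "bound": "gt", "threshold": 6}]}}.
#' @param path JSON file path.
#' @return An [observable_set()].
#' @export
read_constraints <- function(path) {
  x <- jsonlite::fromJSON(path)
  observable_set(waxs = x$waxs, contacts = x$contacts)
}

#' Enumerate candidate fibril topologies
#'
#' Cartesian product of the in-sheet arrangement, the sheet orientation and
#' integer registry offsets in \code{[-max_offset, max_offset]}. For parallel
#' in-sheet arrangements the facing-pair map depends only on |offset|, so
#' negative offsets are deduplicated away; each antiparallel offset gives a
#' distinct head-to-tail facing map and is kept. At \code{max_offset = 0} the
#' enumeration yields the four in-register candidate architectures.
#'
#' @param max_offset Maximum |registry offset| in residues (>= 0).
#' @param n_strands,n_sheets Lattice dimensions attached to each topology.
#' @param dedup Drop offsets equivalent under the facing-map symmetry
#'   (default TRUE).
#' @return A tibble with columns \code{in_sheet}, \code{sheet_orientation},
#'   \code{registry_offset}.
#' @export
enumerate_topologies <- function(max_offset = 0L, n_strands = 6L,
                                 n_sheets = 2L, dedup = TRUE) {
  stopifnot(max_offset >= 0)
  offs <- seq.int(-max_offset, max_offset)
  grid <- tidyr::expand_grid(
    in_sheet = c("parallel", "antiparallel"),
    sheet_orientation = c("parallel", "antiparallel"),
    registry_offset = as.integer(offs)
  )
  if (dedup) {
    grid <- dplyr::filter(grid,
      .data$in_sheet == "antiparallel" | .data$registry_offset >= 0)
  }
  grid
}

# facing-pair map of residue indices between adjacent strands; used by the
# enumeration dedup test and available to oracles
facing_map <- function(L, in_sheet, registry_offset) {
  i <- seq_len(L)
  j <- if (in_sheet == "antiparallel") L + 1L - i + registry_offset
       else i + registry_offset
  j[j < 1L | j > L] <- NA_integer_
  j
}

#' Score one topology against a constraint set
#'
#' Builds the idealized lattice for the topology, then checks each WAXS
#' constraint by whether a predicted repeat falls within \code{tol} of the
#' stated d-spacing (an "absent" constraint is satisfied only when none
#' does — absence is evidence, as in the 9.4 A argument for parallel
#' strands), and each contact constraint by comparing
#' [residue_pair_distance()] with its threshold. The score is
#' \code{n_satisfied - n_violated}. An optional coarse electrostatic bonus
#' (+1 per oppositely charged terminal pair within 8 A across sheets) can be
#' enabled; it is off by default so the core ranking reflects only measured
#' constraints.
#'
#' @param p A \code{peptide} or sequence string.
#' @param topo A [topology()] (or one row of [enumerate_topologies()]).
#' @param obs An [observable_set()].
#' @param spec A [lattice_spec()].
#' @param tol WAXS d-spacing matching tolerance in A (default 0.2).
#' @param electrostatic_bonus Add the cross-sheet terminal-pair bonus.
#' @return A one-row tibble with the topology fields, \code{n_satisfied},
#'   \code{n_violated}, \code{score} and a \code{detail} list-column holding
#'   the per-constraint record (description, computed value, satisfied).
#' @export
score_topology <- function(p, topo, obs, spec = lattice_spec(), tol = 0.2,
                           electrostatic_bonus = FALSE) {
  stopifnot(inherits(obs, "observable_set"))
  if (!inherits(topo, "topology")) {
    topo <- topology(in_sheet = topo$in_sheet,
                     sheet_orientation = topo$sheet_orientation,
                     registry_offset = topo$registry_offset)
  }
  p <- as_peptide(p)
  repeats <- predict_waxs_repeats(topo, spec)
  model <- NULL
  detail <- list()
  for (i in seq_len(nrow(obs$waxs))) {
    d <- obs$waxs$d[i]
    matched <- any(abs(repeats$d - d) <= tol)
    ok <- matched == obs$waxs$present[i]
    detail[[length(detail) + 1L]] <- tibble::tibble(
      constraint = sprintf("waxs %.1f A %s", d,
                           if (obs$waxs$present[i]) "present" else "absent"),
      value = if (matched) repeats$d[which.min(abs(repeats$d - d))] else NA_real_,
      satisfied = ok)
  }
  for (i in seq_len(nrow(obs$contacts))) {
    cc <- obs$contacts[i, ]
    if (is.null(model)) model <- build_lattice(p, topo, spec)
    dist <- residue_pair_distance(model, cc$a, cc$b, scope = cc$scope)
    ok <- if (cc$bound == "lt") dist < cc$threshold else dist > cc$threshold
    detail[[length(detail) + 1L]] <- tibble::tibble(
      constraint = sprintf("contact %s-%s %s %.1f A", cc$a, cc$b, cc$bound,
                           cc$threshold),
      value = dist, satisfied = ok)
  }
  detail <- if (length(detail)) {
    dplyr::bind_rows(detail)
  } else {
    tibble::tibble(constraint = character(), value = numeric(),
                   satisfied = logical())
  }
  n_sat <- sum(detail$satisfied)
  n_vio <- sum(!detail$satisfied)
  score <- n_sat - n_vio
  if (electrostatic_bonus) {
    if (is.null(model)) model <- build_lattice(p, topo, spec)
    score <- score + terminal_pair_bonus(model, p)
  }
  tibble::tibble(in_sheet = topo$in_sheet,
                 sheet_orientation = topo$sheet_orientation,
                 registry_offset = topo$registry_offset,
                 n_satisfied = n_sat, n_violated = n_vio, score = score,
                 detail = list(detail))
}

# +1 per oppositely charged terminal pair within 8 A across sheets
terminal_pair_bonus <- function(model, p) {
  nt <- p$number[1]; ct <- p$number[nrow(p)]
  a <- model[model$number == nt & model$atom == "BB", ]
  b <- model[model$number == ct & model$atom == "BB", ]
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  cross <- outer(a$sheet, b$sheet, "!=")
  sum(cross & d2 <= 64)
}

#' Rank candidate topologies against observables
#'
#' Scores every enumerated topology with [score_topology()] and sorts by
#' descending score, with deterministic tie-breaking: fewer violations,
#' smaller |registry offset|, parallel before antiparallel (in-sheet, then
#' sheet orientation).
#'
#' @inheritParams score_topology
#' @param max_offset Maximum |registry offset| enumerated.
#' @return A tibble of scored topologies, best first, with a \code{rank}
#'   column.
#' @examples
#' obs <- observable_set(
#'   waxs = data.frame(d = c(4.7, 10.3, 9.4), present = c(TRUE, TRUE, FALSE)),
#'   contacts = data.frame(a = "L28", b = "F34", bound = "gt", threshold = 6))
#' rank_topologies("RKKLQDVHNFVAL", obs)
#' @export
rank_topologies <- function(p, obs, spec = lattice_spec(), max_offset = 0L,
                            tol = 0.2, electrostatic_bonus = FALSE) {
  cands <- enumerate_topologies(max_offset)
  scored <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
    score_topology(p, cands[i, ], obs, spec, tol, electrostatic_bonus)
  })
  scored <- dplyr::arrange(scored,
    dplyr::desc(.data$score), .data$n_violated, abs(.data$registry_offset),
    .data$in_sheet != "parallel", .data$sheet_orientation != "parallel")
  dplyr::mutate(scored, rank = dplyr::row_number(), .before = 1)
}
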