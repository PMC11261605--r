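AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", AZO = "AZO"
)

#' Geometric parameters of the idealized cross-beta lattice
#'
#' Spacings of the coarse fibril lattice, with defaults taken from the WAXS
#' assignments of cross-beta amyloid: 4.7 A between adjacent beta-strands
#' within a sheet, 10.3 A between adjacent sheets, 3.4 A rise per residue
#' along the strand, and a 3.8 A target for azobenzene pi-stacking (which
#' conflicts with the 4.7 A strand spacing; the mismatch is flagged on the
#' built model, not resolved geometrically).
#'
#' @param d_strand Interstrand spacing within a sheet (A).
#' @param d_sheet Intersheet spacing (A); must exceed \code{d_pi}.
#' @param residue_rise Rise per residue along the strand axis (A).
#' @param d_pi Target azobenzene ring-stacking distance (A).
#' @param sidechain_offset Sidechain centroid displacement normal to the
#'   sheet plane (A).
#' @return A list of class \code{"lattice_spec"}.
#' @export
lattice_spec <- function(d_strand = 4.7, d_sheet = 10.3, residue_rise = 3.4,
                         d_pi = 3.8, sidechain_offset = 2.5) {
  stopifnot(d_strand > 0, d_sheet > 0, residue_rise > 0, d_pi > 0,
            sidechain_offset > 0)
  if (!(d_pi < d_sheet)) rlang::abort("d_pi must be smaller than d_sheet")
  structure(list(d_strand = d_strand, d_sheet = d_sheet,
                 residue_rise = residue_rise, d_pi = d_pi,
                 sidechain_offset = sidechain_offset),
            class = "lattice_spec")
}

#' Discrete fibril architecture choice
#'
#' @param in_sheet Strand arrangement within a sheet: \code{"parallel"} or
#'   \code{"antiparallel"}.
#' @param sheet_orientation Relative orientation of adjacent sheets.
#' @param registry_offset Integer registry shift (residues) of alternate
#'   strands; 0 is in-register.
#' @param n_strands Strands per sheet (>= 2 for in-sheet observables).
#' @param n_sheets Number of sheets.
#' @return A list of class \code{"topology"}.
#' @export
topology <- function(in_sheet = c("parallel", "antiparallel"),
                     sheet_orientation = c("antiparallel", "parallel"),
                     registry_offset = 0L, n_strands = 6L, n_sheets = 2L) {
  in_sheet <- match.arg(in_sheet)
  sheet_orientation <- match.arg(sheet_orientation)
  stopifnot(registry_offset == round(registry_offset), n_sheets >= 1)
  if (n_strands < 1) rlang::abort("n_strands must be at least 1")
  structure(list(in_sheet = in_sheet, sheet_orientation = sheet_orientation,
                 registry_offset = as.integer(registry_offset),
                 n_strands = as.integer(n_strands),
                 n_sheets = as.integer(n_sheets)),
            class = "topology")
}

# x-coordinates (in residue_rise units) of residue indices 1..L on one strand
strand_positions <- function(L, flipped, offset_units) {
  i <- seq_len(L)
  if (flipped) (L - i) + offset_units else (i - 1) + offset_units
}

#' Build an idealized cross-beta fibril pseudo-atom model
#'
#' Places one backbone point and one sidechain centroid per residue (plus two
#' ring centroids per azobenzene pseudo-residue) on an ideal lattice: strands
#' run along x at \code{residue_rise} pitch, stack along y at \code{d_strand}
#' within a sheet, and sheets stack along z at \code{d_sheet}. Antiparallel
#' in-sheet arrangements flip alternate strands (so residue \code{i} of an
#' up-strand faces residue \code{L + 1 - i + registry_offset} of its
#' neighbours); antiparallel sheet orientation flips alternate sheets.
#' Sidechain centroids alternate above/below the sheet plane with residue
#' parity (beta-pleat); azobenzene ring centroids sit along the strand axis so
#' that in-register stacking gives a ring-ring separation equal to
#' \code{d_strand} — the mismatch with the \code{d_pi} stacking target is
#' recorded in the \code{"pi_mismatch"} attribute.
#'
#' @param p A \code{peptide} or sequence string.
#' @param topo A [topology()].
#' @param spec A [lattice_spec()].
#' @return A tibble of class \code{"lattice_model"}, one row per pseudo-atom,
#'   with columns \code{sheet}, \code{strand}, \code{number},
#'   \code{sublabel}, \code{label}, \code{code}, \code{atom} (\code{"BB"}
#'   backbone, \code{"SC"} sidechain centroid, \code{"R1"}/\code{"R2"} azo
#'   ring centroids), \code{x}, \code{y}, \code{z} (A). Attributes:
#'   \code{topology}, \code{spec}, \code{peptide}, \code{pi_mismatch}.
#' @export
build_lattice <- function(p, topo = topology(), spec = lattice_spec()) {
  p <- as_peptide(p)
  stopifnot(inherits(topo, "topology"), inherits(spec, "lattice_spec"))
  L <- nrow(p)
  if (abs(topo$registry_offset) >= L) {
    rlang::abort("|registry_offset| must be smaller than the peptide length")
  }
  rows <- vector("list", topo$n_sheets * topo$n_strands)
  idx <- 0L
  parity <- ifelse(seq_len(L) %% 2 == 0, 1, -1)
  ring_dx <- 2.2  # half-separation of the two azo ring centroids along x
  for (k in seq_len(topo$n_sheets)) {
    sheet_flip <- topo$sheet_orientation == "antiparallel" && k %% 2 == 0
    for (s in seq_len(topo$n_strands)) {
      strand_flip <- topo$in_sheet == "antiparallel" && s %% 2 == 0
      flipped <- xor(sheet_flip, strand_flip)
      off_units <- if (s %% 2 == 0) topo$registry_offset else 0L
      xs <- strand_positions(L, flipped, off_units) * spec$residue_rise
      y <- (s - 1) * spec$d_strand
      z0 <- (k - 1) * spec$d_sheet
      sc_z <- z0 + parity * spec$sidechain_offset
      base <- tibble::tibble(
        sheet = k, strand = s,
        number = rep(p$number, 2), sublabel = rep(p$sublabel, 2),
        label = rep(p$label, 2), code = rep(p$code, 2),
        atom = rep(c("BB", "SC"), each = L),
        x = rep(xs, 2), y = y, z = c(rep(z0, L), sc_z)
      )
      azo <- which(p$code == "AZO")
      if (length(azo)) {
        ring <- tibble::tibble(
          sheet = k, strand = s,
          number = rep(p$number[azo], 2),
          sublabel = rep(p$sublabel[azo], 2),
          label = rep(p$label[azo], 2), code = "AZO",
          atom = rep(c("R1", "R2"), each = length(azo)),
          x = c(xs[azo] - ring_dx, xs[azo] + ring_dx),
          y = y, z = rep(sc_z[azo], 2)
        )
        base <- dplyr::bind_rows(base, ring)
      }
      idx <- idx + 1L
      rows[[idx]] <- base
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("lattice_model", class(out)),
            topology = topo, spec = spec, peptide = p,
            pi_mismatch = abs(spec$d_strand - spec$d_pi) > 1e-9)
}

#' Predict the diffraction repeats implied by a topology
#'
#' Maps a lattice architecture to the d-spacings its repeating units produce:
#' the interstrand spacing and the intersheet spacing are always present, and
#' an antiparallel in-sheet arrangement additionally produces the two-strand
#' repeat at twice the interstrand spacing (the diagnostic reflection at
#' 9.4 A for the default 4.7 A spacing). Parallel sheets produce no repeat
#' near that position.
#'
#' @param topo A [topology()].
#' @param spec A [lattice_spec()].
#' @return A tibble with columns \code{d} (A), \code{present} and
#'   \code{assignment}.
#' @export
predict_waxs_repeats <- function(topo = topology(), spec = lattice_spec()) {
  stopifnot(inherits(topo, "topology"), inherits(spec, "lattice_spec"))
  out <- tibble::tibble(
    d = c(spec$d_strand, spec$d_sheet),
    present = TRUE,
    assignment = c("interstrand spacing", "intersheet spacing")
  )
  if (topo$in_sheet == "antiparallel") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      d = 2 * spec$d_strand, present = TRUE,
      assignment = "two-strand antiparallel repeat"))
  }
  dplyr::arrange(out, .data$d)
}

resolve_residue <- function(m, res) {
  if (is.numeric(res)) {
    hit <- m$number == res & is.na(m$sublabel)
  } else {
    hit <- m$label == res
    if (!any(hit)) {
      num <- suppressWarnings(as.integer(gsub("[^0-9]", "", res)))
      if (!is.na(num)) hit <- m$number == num & is.na(m$sublabel)
    }
  }
  if (!any(hit)) {
    rlang::abort(sprintf("residue '%s' not found in the model", res))
  }
  hit
}

#' Minimum inter-copy distance between two residues
#'
#' Minimum Euclidean distance over all pseudo-atom pairs (backbone, sidechain
#' centroid, ring points) between copies of the two residues sitting on
#' distinct strands: within the same sheet (\code{"inter_strand"}), on
#' different sheets (\code{"inter_sheet"}), or on any distinct strand
#' (\code{"any"}). This is the quantity a cross-peak in a spin-diffusion
#' spectrum constrains (below ~6 A) or an absent cross-peak bounds from below.
#'
#' @param m A [build_lattice()] model.
#' @param resA,resB Residue identifiers: a residue number (28) or label
#'   (\code{"L28"}, \code{"AZO31"}).
#' @param scope \code{"inter_strand"}, \code{"inter_sheet"} or \code{"any"}.
#' @return Minimum distance in A.
#' @export
residue_pair_distance <- function(m, resA, resB,
                                  scope = c("inter_strand", "inter_sheet", "any")) {
  stopifnot(inherits(m, "lattice_model"))
  scope <- match.arg(scope)
  a <- m[resolve_residue(m, resA), ]
  b <- m[resolve_residue(m, resB), ]
  keep <- switch(scope,
    inter_strand = outer(a$sheet, b$sheet, "==") & outer(a$strand, b$strand, "!="),
    inter_sheet = outer(a$sheet, b$sheet, "!="),
    any = !(outer(a$sheet, b$sheet, "==") & outer(a$strand, b$strand, "=="))
  )
  if (!any(keep)) {
    rlang::abort(sprintf("no residue copies on distinct strands (scope '%s')",
                         scope))
  }
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  sqrt(min(d2[keep]))
}

#' Write a lattice model as a pseudo-atom PDB file
#'
#' Backbone points are written as CA, sidechain centroids as CB and the two
#' azobenzene ring centroids as C1/C2 dummy atoms; each strand is a chain and
#' each sheet a segment (segid \code{S<k>}). An inserted photoswitch's
#' sub-label (e.g. \code{"28a"}) becomes a PDB insertion code.
#'
#' @param m A [build_lattice()] model.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(m, path) {
  stopifnot(inherits(m, "lattice_model"))
  topo <- attr(m, "topology")
  chain_of <- function(sheet, strand) {
    id <- (sheet - 1) * topo$n_strands + strand
    c(LETTERS, letters, 0:9)[id]
  }
  atom_name <- c(BB = "CA", SC = "CB", R1 = "C1", R2 = "C2")
  ord <- order(m$sheet, m$strand, m$number, match(m$atom, names(atom_name)))
  mm <- m[ord, ]
  lines <- character(nrow(mm))
  for (i in seq_len(nrow(mm))) {
    r <- mm[i, ]
    icode <- if (!is.na(r$sublabel)) substr(r$sublabel, nchar(r$sublabel), nchar(r$sublabel)) else " "
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
      i %% 100000, atom_name[[r$atom]], AA_THREE[[r$code]],
      chain_of(r$sheet, r$strand), r$number, icode,
      r$x, r$y, r$z, 1, 0, sprintf("S%d", r$sheet), "C")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a pseudo-atom PDB file written by [write_model()]
#'
#' @param path PDB file path.
#' @return A tibble with columns \code{serial}, \code{atom}, \code{resname},
#'   \code{chain}, \code{number}, \code{icode}, \code{x}, \code{y}, \code{z},
#'   \code{segid}.
#' @export
read_model <- function(path) {
  ll <- readLines(path)
  ll <- ll[startsWith(ll, "ATOM")]
  tibble::tibble(
    serial = as.integer(substr(ll, 7, 11)),
    atom = trimws(substr(ll, 13, 16)),
    resname = trimws(substr(ll, 18, 20)),
    chain = substr(ll, 22, 22),
    number = as.integer(substr(ll, 23, 26)),
    icode = trimws(substr(ll, 27, 27)),
    x = as.numeric(substr(ll, 31, 38)),
    y = as.numeric(substr(ll, 39, 46)),
    z = as.numeric(substr(ll, 47, 54)),
    segid = trimws(substr(ll, 73, 76))
  )
}
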