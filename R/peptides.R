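#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Parent fragment of the family: residues 25-37 of parathyroid hormone.
PTH25_37 <- "RKKLQDVHNFVAL"

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Side-chain pKa values used for formal (integer) charge assignment.
SIDECHAIN_PKA <- list(
  basic  = c(R = 12.5, K = 10.5, H = 6.0),
  acidic = c(D = 3.9, E = 4.1, C = 8.3, Y = 10.1)
)
PKA_NTERM <- 9.0
PKA_CTERM <- 3.1

POLAR_SET <- c("S", "T", "C", "Y", "N", "Q", "H", "W")

#' Parse a peptide sequence with an azobenzene (AMPB) pseudo-residue
#'
#' Sequences use one-letter amino-acid codes with the photoswitch written as
#' the token \code{-Azo-}, the dialect of the peptide design table (e.g.
#' \code{"RKKLQD-Azo-HNFVAL"} for P4). Residues are numbered consecutively from
#' \code{offset} (25 for this peptide family). When a \code{parent} sequence is
#' supplied (default: the unmodified PTH 25-37 fragment), the modification is
#' inferred by anchoring the flanks of the Azo token on the parent: if the
#' flanks cover the whole parent the photoswitch is an \emph{insertion} and is
#' given a sub-label such as \code{"28a"} (so downstream residue numbers are
#' unchanged); otherwise it is an \emph{exchange} and takes the number of the
#' first replaced residue (numbering then skips any further replaced
#' positions, as in the double exchange D30,V31 -> Azo).
#'
#' @param text Sequence string; one-letter codes plus optional \code{-Azo-}.
#' @param offset Biological number of the first residue (default 25).
#' @param name Optional short label (e.g. "P4").
#' @param parent Parent sequence used to infer the modification record, or
#'   \code{NA} to skip inference (residues then numbered consecutively).
#' @return A tibble of class \code{"peptide"} with one row per residue and
#'   columns \code{code} (one-letter code or \code{"AZO"}), \code{number}
#'   (integer residue number), \code{sublabel} (e.g. \code{"28a"} for an
#'   inserted photoswitch, otherwise \code{NA}) and \code{label} (e.g.
#'   \code{"L28"}). Attributes: \code{name}, \code{offset},
#'   \code{modification} (\code{NULL}, or a list with \code{kind}
#'   (\code{"insertion"}/\code{"exchange"}) and \code{anchor} residues).
#' @examples
#' parse_peptide("RKKLQDVHNFVAL", name = "PTH25-37")
#' parse_peptide("RKKLQD-Azo-HNFVAL", name = "P4")
#' @export
parse_peptide <- function(text, offset = 25L, name = NULL, parent = PTH25_37) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) abort("empty sequence", class = "photofibril_parse_error")
  codes <- tokenize_sequence(text)
  n_azo <- sum(codes == "AZO")

  modification <- NULL
  numbers <- seq_along(codes) + offset - 1L
  sublabel <- rep(NA_character_, length(codes))

  parent_codes <- if (length(parent) == 1 && !is.na(parent)) {
    tokenize_sequence(parent)
  }
  if (!is.null(parent_codes) && n_azo == 1 &&
      !identical(codes, parent_codes)) {
    azo_at <- which(codes == "AZO")
    pre <- codes[seq_len(azo_at - 1L)]
    post <- if (azo_at < length(codes)) codes[(azo_at + 1L):length(codes)] else character()
    lp <- length(parent_codes)
    ok_pre <- length(pre) <= lp && identical(pre, parent_codes[seq_along(pre)])
    ok_post <- length(post) <= lp &&
      identical(post, parent_codes[seq.int(lp - length(post) + 1L, length.out = length(post))])
    if (!ok_pre || !ok_post || length(pre) + length(post) > lp) {
      abort("sequence cannot be reconciled with the parent sequence",
            class = "photofibril_parse_error")
    }
    np <- length(pre); ns <- length(post)
    pre_numbers <- seq_len(np) + offset - 1L
    post_numbers <- seq.int(lp - ns + 1L, lp) + offset - 1L
    if (np + ns == lp) {
      # insertion between parent[np] and parent[np + 1]
      anchor_num <- np + offset - 1L
      numbers <- c(pre_numbers, anchor_num, post_numbers)
      sublabel[azo_at] <- paste0(anchor_num, "a")
      modification <- list(
        kind = "insertion",
        anchor = c(
          paste0(parent_codes[np], anchor_num),
          paste0(parent_codes[np + 1L], anchor_num + 1L)
        )
      )
    } else {
      # exchange of parent positions (np+1) .. (lp-ns)
      replaced <- seq.int(np + 1L, lp - ns)
      numbers <- c(pre_numbers, replaced[1L] + offset - 1L, post_numbers)
      modification <- list(
        kind = "exchange",
        anchor = paste0(parent_codes[replaced], replaced + offset - 1L)
      )
    }
  }

  label <- ifelse(
    codes == "AZO",
    paste0("AZO", ifelse(is.na(sublabel), numbers, sublabel)),
    paste0(codes, ifelse(is.na(sublabel), numbers, sublabel))
  )
  out <- tibble(code = codes, number = as.integer(numbers),
                sublabel = sublabel, label = label)
  structure(out,
            class = c("peptide", class(out)),
            name = name %||% NA_character_,
            offset = as.integer(offset),
            modification = modification)
}

tokenize_sequence <- function(text) {
  text <- gsub("\\s", "", text)
  parts <- strsplit(text, "-Azo-", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty piece; restore it so "...F-Azo-" errors sanely
  n_azo <- lengths(regmatches(text, gregexpr("-Azo-", text, fixed = TRUE)))
  if (length(parts) < n_azo + 1L) parts <- c(parts, rep("", n_azo + 1L - length(parts)))
  codes <- character()
  for (i in seq_along(parts)) {
    chars <- strsplit(parts[[i]], "")[[1]]
    bad <- which(!(chars %in% AA_CODES))
    if (length(bad)) {
      abort(sprintf("unknown residue token '%s' at position %d of segment %d",
                    chars[bad[1]], bad[1], i),
            class = "photofibril_parse_error")
    }
    codes <- c(codes, chars)
    if (i < length(parts)) codes <- c(codes, "AZO")
  }
  if (!length(codes)) abort("empty sequence", class = "photofibril_parse_error")
  codes
}

#' Serialize a peptide back to the sequence dialect
#'
#' Inverse of [parse_peptide()]: one-letter codes with the photoswitch written
#' as \code{-Azo-}.
#' @param p A \code{peptide}.
#' @return A string.
#' @export
format_peptide <- function(p) {
  stopifnot(inherits(p, "peptide"))
  out <- ""
  for (code in p$code) {
    out <- if (code == "AZO") paste0(out, "-Azo-") else paste0(out, code)
  }
  out
}

#' @export
print.peptide <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("<peptide%s> %d residues, offset %d: %s\n",
              if (!is.na(nm)) paste0(" ", nm) else "",
              nrow(x), attr(x, "offset"), format_peptide(x)))
  mod <- attr(x, "modification")
  if (!is.null(mod)) {
    cat(sprintf("  modification: %s (%s)\n", mod$kind,
                paste(mod$anchor, collapse = ", ")))
  }
  invisible(x)
}

as_peptide <- function(p, ...) {
  if (inherits(p, "peptide")) p else parse_peptide(p, ...)
}

#' Formal per-residue charges and physicochemical class counts
#'
#' Assigns formal integer charges by comparing the stated pH with side-chain
#' pKa values (R, K charged +1 and D, E charged -1 at pH 7.4; H neutral at
#' pH 7.4, its pKa ~6 making it the borderline case). Terminal charges (free
#' amine N-terminus, free acid C-terminus) are reported separately so that the
#' side-chain counts match sequence-based reasoning such as "three positive
#' charges (RKK)". The azobenzene pseudo-residue is uncharged and classified
#' hydrophobic.
#'
#' @param p A \code{peptide} or sequence string.
#' @param pH Solution pH in (0, 14); default 7.4.
#' @return A tibble of class \code{"charge_profile"} with per-residue columns
#'   \code{label}, \code{number}, \code{code}, \code{charge}, \code{class}
#'   (positive/negative/polar/hydrophobic). Attributes: \code{counts} (named
#'   integer vector \code{n_positive}, \code{n_negative}, \code{n_polar},
#'   \code{n_hydrophobic}), \code{terminal_charges} (named numeric,
#'   \code{n_term}/\code{c_term}), \code{pH}.
#' @examples
#' prof <- charge_profile("RKKLQDVHNFVAL")
#' attr(prof, "counts")
#' @export
charge_profile <- function(p, pH = 7.4) {
  p <- as_peptide(p)
  stopifnot(pH > 0, pH < 14)
  charge <- vapply(p$code, function(code) {
    if (code %in% names(SIDECHAIN_PKA$basic)) {
      if (pH < SIDECHAIN_PKA$basic[[code]]) 1 else 0
    } else if (code %in% names(SIDECHAIN_PKA$acidic)) {
      if (pH > SIDECHAIN_PKA$acidic[[code]]) -1 else 0
    } else 0
  }, numeric(1), USE.NAMES = FALSE)
  cls <- ifelse(charge > 0, "positive",
         ifelse(charge < 0, "negative",
         ifelse(p$code %in% POLAR_SET, "polar", "hydrophobic")))
  counts <- c(
    n_positive = sum(cls == "positive"),
    n_negative = sum(cls == "negative"),
    n_polar = sum(cls == "polar"),
    n_hydrophobic = sum(cls == "hydrophobic")
  )
  terminal <- c(
    n_term = if (pH < PKA_NTERM) 1 else 0,
    c_term = if (pH > PKA_CTERM) -1 else 0
  )
  out <- tibble(label = p$label, number = p$number, code = p$code,
                charge = charge, class = cls)
  structure(out, class = c("charge_profile", class(out)),
            counts = counts, terminal_charges = terminal, pH = pH)
}

#' Sliding-window hydropathy track
#'
#' Windowed mean of a per-residue hydropathy scale (Kyte-Doolittle by
#' default). The azobenzene pseudo-residue takes \code{azo_score}, which
#' defaults above the most hydrophobic natural residue (I, 4.5) to encode the
#' observation that the photoswitch increases the peptide's overall
#' hydrophobicity. The most hydrophobic window locates the aggregation-prone
#' region of the sequence.
#'
#' @param p A \code{peptide} or sequence string.
#' @param window Window length, between 1 and the sequence length.
#' @param azo_score Hydropathy score assigned to AZO (default 4.6).
#' @param scale Named per-residue scale (default Kyte-Doolittle).
#' @return A tibble of class \code{"hydropathy_track"} with one row per
#'   window: \code{start_number}, \code{center_number}, \code{end_number},
#'   \code{score}. Attributes: \code{window}, \code{argmax} (numbers spanned
#'   by the highest-scoring window).
#' @examples
#' hydropathy_track("RKKLQDVHNFVAL", window = 5)
#' @export
hydropathy_track <- function(p, window = 5L, azo_score = 4.6,
                             scale = KD_SCALE) {
  p <- as_peptide(p)
  n <- nrow(p)
  if (window < 1 || window > n) {
    abort(sprintf("window (%d) must be between 1 and the sequence length (%d)",
                  window, n))
  }
  per_res <- ifelse(p$code == "AZO", azo_score, unname(scale[p$code]))
  if (anyNA(per_res)) abort("scale is missing a residue code")
  score <- vapply(seq_len(n - window + 1L), function(i) {
    mean(per_res[i:(i + window - 1L)])
  }, numeric(1))
  starts <- seq_len(n - window + 1L)
  imax <- which.max(score)
  out <- tibble(
    start_number = p$number[starts],
    center_number = p$number[starts + (window - 1L) %/% 2L],
    end_number = p$number[starts + window - 1L],
    score = score
  )
  structure(out, class = c("hydropathy_track", class(out)),
            window = as.integer(window),
            argmax = c(out$start_number[imax], out$end_number[imax]))
}

#' @rdname hydropathy_track
#' @param object,... An object and further arguments passed to methods.
#' @exportS3Method ggplot2::autoplot
autoplot.hydropathy_track <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$center_number, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "residue number (window center)",
                  y = sprintf("mean hydropathy (window %d)",
                              attr(object, "window")))
}
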