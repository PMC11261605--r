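# Independent oracles used across the suite. These are deliberately written
# from the model definitions, not from the package's internals.

# Moment equations of nucleation-elongation with explicit microscopic rates:
#   dP/dt = k_n m^n_c + k_2 m^n_2 M,  dM/dt = 2 k_plus m P,  m = m_tot - M.
# The microscopic rates are chosen to reproduce the combined rates
# lam = sqrt(2 k_plus k_n m_tot^n_c) and kap = sqrt(2 k_plus k_2 m_tot^(n_2+1))
# with m_tot = 1 and an arbitrary k_plus (the mass trace depends only on
# lam and kap given the orders). Fixed-step RK4.
ode_oracle_mass <- function(times, lam, kap, n_c = 2, n_2 = 2,
                            k_plus = 0.5, h = NULL) {
  k_n <- lam^2 / (2 * k_plus)
  k_2 <- kap^2 / (2 * k_plus)
  if (is.null(h)) h <- 0.02 / max(lam, kap, 0.05)
  f <- function(s) {
    m <- max(1 - s[2], 0)
    c(k_n * m^n_c + k_2 * m^n_2 * s[2], 2 * k_plus * m * s[1])
  }
  grid <- sort(unique(times))
  res <- numeric(length(grid))
  s <- c(0, 0); t <- 0
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    while (t < g - 1e-12) {
      hh <- min(h, g - t)
      k1 <- f(s); k2 <- f(s + hh / 2 * k1)
      k3 <- f(s + hh / 2 * k2); k4 <- f(s + hh * k3)
      s <- s + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    res[gi] <- min(s[2], 1)
  }
  res[match(times, grid)]
}

# Brute-force minimum distance between two residues over all atom pairs on
# distinct strands, scanning the model table directly.
brute_min_dist <- function(m, lab_a, lab_b, scope = "inter_strand") {
  a <- m[m$label == lab_a, ]
  b <- m[m$label == lab_b, ]
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      same_strand <- a$sheet[i] == b$sheet[j] && a$strand[i] == b$strand[j]
      ok <- switch(scope,
        inter_strand = a$sheet[i] == b$sheet[j] && a$strand[i] != b$strand[j],
        inter_sheet = a$sheet[i] != b$sheet[j],
        any = !same_strand)
      if (!ok) next
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# Facing-pair map between adjacent strands, re-derived from the definitions.
oracle_facing_pairs <- function(L, in_sheet, offset) {
  pairs <- list()
  for (i in seq_len(L)) {
    j <- if (in_sheet == "antiparallel") L + 1 - i + offset else i + offset
    if (j >= 1 && j <= L) {
      pairs[[length(pairs) + 1L]] <- sort(c(i, j))
    }
  }
  unique(pairs)
}

# Independent constraint scorer: derives repeats and distances from first
# principles (doubling rule; brute-force scan of a freshly built model).
oracle_score <- function(p, in_sheet, sheet_orientation, offset, obs,
                         spec = lattice_spec(), tol = 0.2) {
  reps <- c(spec$d_strand, spec$d_sheet)
  if (in_sheet == "antiparallel") reps <- c(reps, 2 * spec$d_strand)
  n_sat <- 0L; n_vio <- 0L
  for (i in seq_len(nrow(obs$waxs))) {
    hit <- any(abs(reps - obs$waxs$d[i]) <= tol)
    if (hit == obs$waxs$present[i]) n_sat <- n_sat + 1L else n_vio <- n_vio + 1L
  }
  if (nrow(obs$contacts)) {
    m <- build_lattice(p, topology(in_sheet = in_sheet,
                                   sheet_orientation = sheet_orientation,
                                   registry_offset = offset), spec)
    for (i in seq_len(nrow(obs$contacts))) {
      cc <- obs$contacts[i, ]
      d <- brute_min_dist(m, cc$a, cc$b,
                          scope = if ("scope" %in% names(cc)) cc$scope else "inter_strand")
      ok <- if (cc$bound == "lt") d < cc$threshold else d > cc$threshold
      if (ok) n_sat <- n_sat + 1L else n_vio <- n_vio + 1L
    }
  }
  c(n_satisfied = n_sat, n_violated = n_vio, score = n_sat - n_vio)
}

P4_SEQ <- "RKKLQD-Azo-HNFVAL"
PTH_SEQ <- "RKKLQDVHNFVAL"
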