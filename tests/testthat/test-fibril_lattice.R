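test_that("in-register stacking separates identical residues by d_strand", {
  m <- build_lattice(PTH_SEQ, topology(in_sheet = "parallel"), lattice_spec())
  bb <- m[m$atom == "BB" & m$sheet == 1 & m$label == "L28", ]
  expect_equal(abs(bb$y[bb$strand == 2] - bb$y[bb$strand == 1]), 4.7)
  expect_equal(bb$x[bb$strand == 2], bb$x[bb$strand == 1])
  expect_equal(residue_pair_distance(m, "L28", "L28", "inter_strand"), 4.7)
  # adjacent backbone points along a strand are residue_rise apart
  s1 <- m[m$atom == "BB" & m$sheet == 1 & m$strand == 1, ]
  s1 <- s1[order(s1$x), ]
  expect_true(all(abs(diff(s1$x) - 3.4) < 1e-12))
  # adjacent sheets are d_sheet apart
  expect_equal(sort(unique(m$z[m$atom == "BB"])), c(0, 10.3))
})

test_that("antiparallel head-to-tail pairing faces L28 against F34 in a 13-mer", {
  m <- build_lattice(P4_SEQ, topology(in_sheet = "antiparallel",
                                      registry_offset = 0))
  # residue index 4 (L28) of an up-strand shares x with index 10 (F34) of the
  # neighbouring down-strand: 4 = 14 - 10
  l28 <- m[m$label == "L28" & m$atom == "BB" & m$strand == 1 & m$sheet == 1, ]
  f34 <- m[m$label == "F34" & m$atom == "BB" & m$strand == 2 & m$sheet == 1, ]
  expect_equal(l28$x, f34$x)
  expect_equal(residue_pair_distance(m, "L28", "F34", "inter_strand"), 4.7)
  # the facing map is an involution: both directions give the same distance
  expect_equal(residue_pair_distance(m, "F34", "L28", "inter_strand"),
               residue_pair_distance(m, "L28", "F34", "inter_strand"))
})

test_that("atom bookkeeping covers every residue plus the azo ring points", {
  topo <- topology(n_strands = 3, n_sheets = 2)
  m_pth <- build_lattice(PTH_SEQ, topo)
  expect_equal(nrow(m_pth), 3 * 2 * (2 * 13))
  m_p4 <- build_lattice(P4_SEQ, topo)
  expect_equal(nrow(m_p4), 3 * 2 * (2 * 13 + 2))
  expect_equal(sum(m_p4$atom %in% c("R1", "R2")), 3 * 2 * 2)
  # ring points of in-register neighbours stack at d_strand, flagged against
  # the pi-stacking target
  r1 <- m_p4[m_p4$atom == "R1" & m_p4$sheet == 1, ]
  expect_true(attr(m_p4, "pi_mismatch"))
  expect_equal(abs(diff(r1$y[1:2])), 4.7)

  # a single strand is a valid (if observable-free) model
  single <- build_lattice(PTH_SEQ, topology(n_strands = 1))
  expect_equal(nrow(single), 2 * 2 * 13)
  expect_error(residue_pair_distance(single, "L28", "F34", "inter_strand"),
               regexp = "distinct strands")
  expect_error(build_lattice(PTH_SEQ, topology(n_strands = 0)),
               regexp = "n_strands")
  expect_error(residue_pair_distance(m_pth, "L99", "F34"), regexp = "not found")
})

test_that("topology-to-diffraction mapping follows the doubling rule", {
  par <- predict_waxs_repeats(topology(in_sheet = "parallel"), lattice_spec())
  expect_setequal(par$d, c(4.7, 10.3))
  expect_false(any(abs(par$d - 9.4) <= 0.2))
  anti <- predict_waxs_repeats(topology(in_sheet = "antiparallel"),
                               lattice_spec())
  expect_true(any(anti$d == 9.4))
  expect_equal(anti$assignment[anti$d == 9.4], "two-strand antiparallel repeat")
  # parallel repeats are a subset of antiparallel repeats for equal spacings
  expect_true(all(par$d %in% anti$d))
  # doubling tracks the interstrand spacing
  five <- predict_waxs_repeats(topology(in_sheet = "antiparallel"),
                               lattice_spec(d_strand = 5.0))
  expect_true(any(five$d == 10.0))
})

test_that("distances are rigid-motion invariant and match a brute-force scan", {
  m <- build_lattice(P4_SEQ, topology(in_sheet = "antiparallel",
                                      n_strands = 3, n_sheets = 2))
  for (scope in c("inter_strand", "inter_sheet", "any")) {
    expect_equal(residue_pair_distance(m, "L28", "F34", scope),
                 brute_min_dist(m, "L28", "F34", scope), tolerance = 1e-12)
  }
  # rotate + translate every atom and rebuild the distances
  th <- 0.7; ph <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  m2 <- m
  m2$x <- xyz[, 1] + 11.3; m2$y <- xyz[, 2] - 4.2; m2$z <- xyz[, 3] + 0.9
  expect_equal(residue_pair_distance(m2, "L28", "F34", "inter_strand"),
               residue_pair_distance(m, "L28", "F34", "inter_strand"),
               tolerance = 1e-9)
})

test_that("PDB output round-trips with one chain per strand", {
  m <- build_lattice(PTH_SEQ, topology(n_strands = 6, n_sheets = 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(length(unique(back$chain)), 12)
  expect_equal(length(unique(back$segid)), 2)
  expect_equal(nrow(back), nrow(m))
  ord <- order(m$sheet, m$strand, m$number,
               match(m$atom, c("BB", "SC", "R1", "R2")))
  expect_equal(back$x, m$x[ord], tolerance = 1e-3)
  expect_equal(back$y, m$y[ord], tolerance = 1e-3)
  expect_equal(back$z, m$z[ord], tolerance = 1e-3)
  # azo residues emit their two extra ring pseudo-atoms
  m4 <- build_lattice(P4_SEQ, topology(n_strands = 2, n_sheets = 1))
  p4path <- withr::local_tempfile(fileext = ".pdb")
  write_model(m4, p4path)
  b4 <- read_model(p4path)
  expect_equal(sum(b4$atom %in% c("C1", "C2")), 4)
  expect_equal(sum(b4$resname == "AZO"), 2 * 4)
})
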