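test_that("two-node network matches the analytic solution", {
  atoms <- rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0),
                 atom_row("CA", "ALA", "A", 2, 5, 0, 0))
  st <- manual_structure(atoms)
  enm <- build_enm(st, cutoff = 10, mode = "calpha", gamma = 1)
  expect_equal(enm$n_springs, 1L)
  m <- enm_modes(enm)
  nz <- m$eigenvalues[m$eigenvalues > 1e-8 * max(m$eigenvalues)]
  # single spring along the axis: one nonzero mode with eigenvalue 2*gamma
  expect_equal(length(nz), 1L)
  expect_equal(nz, 2, tolerance = 1e-12)
})

test_that("a sub-contact cutoff yields no springs and a zero spectrum", {
  atoms <- rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0),
                 atom_row("CA", "ALA", "A", 2, 5, 0, 0),
                 atom_row("CA", "ALA", "A", 3, 10, 0, 0))
  st <- manual_structure(atoms)
  expect_warning(enm <- build_enm(st, cutoff = 0.5, mode = "calpha"),
                 "no springs")
  expect_true(all(abs(enm$hessian) == 0))
})

test_that("the Hessian is symmetric with zero row-block sums", {
  st <- toy("dsDNA", seed = 1)$structure
  enm <- build_enm(st, cutoff = 10, mode = "calpha")
  H <- enm$hessian
  expect_equal(H, t(H), tolerance = 1e-12)
  n <- nrow(enm$nodes)
  # translation invariance: sum of 3x3 blocks along each block row is zero
  for (i in seq_len(min(n, 5))) {
    ri <- (3 * i - 2):(3 * i)
    s <- matrix(0, 3, 3)
    for (j in seq_len(n)) s <- s + H[ri, (3 * j - 2):(3 * j)]
    expect_lt(max(abs(s)), 1e-10)
  }
})

test_that("connected fixtures have exactly six rigid-body modes", {
  for (kind in c("dsDNA", "ssRNA")) {
    st <- toy(kind, seed = 2)$structure
    m <- enm_modes(build_enm(st, cutoff = 10, mode = "heavy"))
    expect_equal(m$n_zero, 6L)
    nz <- m$eigenvalues[m$eigenvalues > 1e-8 * max(m$eigenvalues)]
    expect_true(all(nz > 0))
  }
})

test_that("the spectrum is invariant under rigid motion and node order", {
  st <- toy("dsDNA", seed = 3)$structure
  m1 <- enm_modes(build_enm(st, mode = "calpha"))
  m2 <- enm_modes(build_enm(rigid_move(st), mode = "calpha"))
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
  expect_equal(m1$s_vib, m2$s_vib, tolerance = 1e-8)
  # permute atom order (per residue blocks preserved by taking CA only)
  a <- st$atoms
  perm <- manual_structure(a[rev(seq_len(nrow(a))), ], "perm")
  m3 <- enm_modes(build_enm(perm, mode = "calpha"))
  expect_equal(m1$eigenvalues, m3$eigenvalues, tolerance = 1e-8)
})

test_that("stiffening reduces vibrational entropy; identity leaves it unchanged", {
  st <- toy("dsDNA", seed = 1)$structure
  expect_equal(vibrational_entropy_change(st, st), 0)
  expect_equal(vibrational_entropy_change(st, rigid_move(st)),
               0, tolerance = 1e-7)
  # five nodes whose spring graph is already at full internal rank with one
  # pair (the longest) disconnected: adding that spring raises eigenvalues
  # (Weyl) without creating new modes, so the entropy strictly drops
  atoms <- rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0),
                 atom_row("CA", "ALA", "A", 2, 3, 0, 0),
                 atom_row("CA", "ALA", "A", 3, 0, 3, 0),
                 atom_row("CA", "ALA", "A", 4, 0, 0, 3),
                 atom_row("CA", "ALA", "A", 5, 3, 3, 3))
  st5 <- manual_structure(atoms)
  loose <- build_enm(st5, cutoff = 4.5, mode = "calpha")
  stiff <- build_enm(st5, cutoff = 6, mode = "calpha")
  expect_equal(stiff$n_springs, loose$n_springs + 1L)
  ml <- enm_modes(loose); ms <- enm_modes(stiff)
  expect_equal(ml$n_zero, 6L)
  expect_equal(ms$n_zero, 6L)
  expect_true(all(ms$eigenvalues >= ml$eigenvalues - 1e-10))
  expect_gt(max(ms$eigenvalues - ml$eigenvalues), 1e-3)
  expect_lt(ms$s_vib, ml$s_vib)
  # uniform stiffening: doubling gamma shifts s_vib by -(m/2) ln 2
  g2 <- build_enm(st5, cutoff = 6, mode = "calpha", gamma = 2)
  m2 <- enm_modes(g2)
  n_modes <- length(ms$eigenvalues) - ms$n_zero
  expect_equal(m2$s_vib, ms$s_vib - n_modes / 2 * log(2), tolerance = 1e-8)
})

test_that("side-chain replacement registers only in heavy-atom mode", {
  st <- toy("dsDNA", seed = 1)$structure
  ir <- interface_residues(st)
  ir <- ir[!(ir$residue_name %in% c("ALA", "GLY")), , drop = FALSE]
  row <- ir[1, ]
  spec <- list(chain_id = row$chain_id, wt = aa3to1(row$residue_name),
               residue_number = row$residue_number, mut = "A")
  mut <- naive_mutant(st, spec)
  expect_equal(vibrational_entropy_change(st, mut, mode = "calpha"), 0)
  d_heavy <- vibrational_entropy_change(st, mut, mode = "heavy")
  expect_true(is.finite(d_heavy))
  expect_false(d_heavy == 0)
})
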