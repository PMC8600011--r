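test_that("naive mutant builder obeys its contracts", {
  st <- toy("dsDNA", seed = 1)$structure
  a <- st$atoms
  prot <- a[st$chains[a$chain_id] == "protein", ]
  # pick a non-Ala, non-Gly site
  resn <- unique(prot[, c("residue_number", "residue_name")])
  row <- resn[!(resn$residue_name %in% c("ALA", "GLY")), ][1, ]
  wt1 <- aa3to1(row$residue_name)

  # self-mutation returns the structure unchanged
  self <- naive_mutant(st, list(chain_id = "A", wt = wt1,
                                residue_number = row$residue_number,
                                mut = wt1))
  expect_identical(self, st)

  # mutation to Ala leaves exactly the 5 alanine heavy atoms
  mutA <- naive_mutant(st, list(chain_id = "A", wt = wt1,
                                residue_number = row$residue_number,
                                mut = "A"))
  ra <- mutA$atoms[mutA$atoms$chain_id == "A" &
                     mutA$atoms$residue_number == row$residue_number, ]
  expect_setequal(ra$name, c("N", "CA", "C", "O", "CB"))
  expect_true(all(ra$residue_name == "ALA"))

  # mutation to Gly removes the side chain entirely
  mutG <- naive_mutant(st, list(chain_id = "A", wt = wt1,
                                residue_number = row$residue_number,
                                mut = "G"))
  rg <- mutG$atoms[mutG$atoms$chain_id == "A" &
                     mutG$atoms$residue_number == row$residue_number, ]
  expect_setequal(rg$name, c("N", "CA", "C", "O"))

  # backbone coordinates identical to wild type for every target
  for (mt in c("A", "W", "R", "S")) {
    if (mt == wt1) next
    mut <- naive_mutant(st, list(chain_id = "A", wt = wt1,
                                 residue_number = row$residue_number,
                                 mut = mt))
    for (nm in c("N", "CA", "C", "O")) {
      w <- a[a$chain_id == "A" & a$residue_number == row$residue_number &
               a$name == nm, c("x", "y", "z")]
      m <- mut$atoms[mut$atoms$chain_id == "A" &
                       mut$atoms$residue_number == row$residue_number &
                       mut$atoms$name == nm, c("x", "y", "z")]
      expect_equal(unlist(w), unlist(m), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
    # the full target side chain is present
    built <- mut$atoms[mut$atoms$chain_id == "A" &
                         mut$atoms$residue_number == row$residue_number, ]
    tmpl <- nabind:::.AA_TEMPLATES[[aa1to3(mt)]]
    expect_setequal(built$name,
                    c("N", "CA", "C", "O",
                      vapply(tmpl, function(e) e[1], character(1))))
  }

  # wild-type letter mismatch is a validation error naming the residue found
  wrong <- setdiff(c("K", "E"), wt1)[1]
  expect_error(naive_mutant(st, list(chain_id = "A", wt = wrong,
                                     residue_number = row$residue_number,
                                     mut = "A")),
               "wild-type mismatch")
})

test_that("substitution features look up the packaged matrices", {
  mats <- substitution_matrices()
  expect_setequal(names(mats), c("blosum62", "hydropathy", "volume"))
  s <- substitution_features("R", "A")
  # value read directly from the shipped matrix file
  hyd_file <- system.file("extdata", "submat_hydropathy.txt",
                          package = "nabind")
  hyd <- as.matrix(read.table(hyd_file, header = TRUE, row.names = 1,
                              check.names = FALSE))
  expect_equal(unname(s["sub:hydropathy"]), hyd["R", "A"])
  # identity substitution under the symmetric matrix hits the diagonal
  expect_equal(unname(substitution_features("W", "W")["sub:blosum62"]),
               mats$blosum62["W", "W"])
  # symmetric matrix: swapping wt/mut preserves the score
  expect_equal(unname(substitution_features("R", "A")["sub:blosum62"]),
               unname(substitution_features("A", "R")["sub:blosum62"]))
  # property-difference matrices are antisymmetric by construction
  expect_equal(unname(substitution_features("R", "A")["sub:volume"]),
               -unname(substitution_features("A", "R")["sub:volume"]))
  expect_error(substitution_features("X", "A"), "non-standard")
})

test_that("assembled vectors follow the schema and zero out on self-mutation", {
  st <- toy("dsDNA", seed = 1)$structure
  ir <- interface_residues(st)
  ir <- ir[!(ir$residue_name %in% c("ALA", "GLY")), , drop = FALSE]
  row <- ir[1, ]
  wt1 <- aa3to1(row$residue_name)
  spec <- list(chain_id = row$chain_id, wt = wt1,
               residue_number = row$residue_number, mut = wt1)
  fv <- assemble_features(st, st, spec)
  expect_equal(names(fv), feature_schema())
  expect_true(all(fv[grepl("^(dsig|nma):", names(fv))] == 0))
  expect_true(all(fv[grepl(":delta$", names(fv))] == 0))
  expect_equal(unname(fv["na:is_rna"]), 0)
  expect_equal(unname(fv["na:is_double"]), 1)
  expect_equal(unname(fv["geo:min_dist_na"]), row$min_distance)

  # real mutation: interaction delta equals the cross-module oracle delta
  spec2 <- list(chain_id = row$chain_id, wt = wt1,
                residue_number = row$residue_number, mut = "A")
  mut <- naive_mutant(st, spec2)
  fv2 <- assemble_features(st, mut, spec2)
  site <- list(chain_id = row$chain_id, residue_number = row$residue_number)
  oracle_delta <- oracle_interaction_counts(mut, "site", site) -
    oracle_interaction_counts(st, "site", site)
  got <- fv2[paste0("int:", interaction_types(), ":delta")]
  expect_equal(unname(got), unname(as.numeric(oracle_delta)))

  # determinism: repeated assembly is bit-identical
  expect_identical(fv2, assemble_features(st, mut, spec2))
})

test_that("aggregation over singles follows the per-feature mode map", {
  st <- toy("dsDNA", seed = 1)$structure
  ir <- interface_residues(st)
  ir <- ir[!(ir$residue_name %in% c("ALA", "GLY")), , drop = FALSE]
  fvs <- lapply(1:2, function(i) {
    row <- ir[i, ]
    spec <- list(chain_id = row$chain_id, wt = aa3to1(row$residue_name),
                 residue_number = row$residue_number, mut = "A")
    assemble_features(st, naive_mutant(st, spec), spec)
  })
  # identity on a single vector
  one <- aggregate_multi(fvs[1], mode = "mean")
  expect_equal(as.numeric(one), as.numeric(fvs[[1]]))
  # mean and sum relate by n
  m <- aggregate_multi(fvs, mode = "mean")
  s <- aggregate_multi(fvs, mode = "sum")
  expect_equal(as.numeric(s), 2 * as.numeric(m))
  # auto mode: counts summed, scores/distances averaged
  auto <- aggregate_multi(fvs)
  expect_equal(unname(auto["geo:min_dist_na"]),
               mean(c(fvs[[1]]["geo:min_dist_na"],
                      fvs[[2]]["geo:min_dist_na"])))
  k <- "int:vdw:wt"
  expect_equal(unname(auto[k]), unname(fvs[[1]][k] + fvs[[2]][k]))
  # permutation invariance
  expect_equal(as.numeric(aggregate_multi(rev(fvs))), as.numeric(auto))
  # schema mismatch errors
  bad <- fvs[[2]][-1]
  expect_error(aggregate_multi(list(fvs[[1]], bad)), "schema mismatch")
})
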