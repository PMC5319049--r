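test_that("parameter validation enforces the slice tiling constraint", {
  p <- classifier_params()
  expect_equal(p$slice_width, 10)
  expect_equal(p$dist_cutoff, 10)
  expect_equal(p$shell_radius, 6)
  expect_equal(p$angle_cutoff_beta, 65)
  expect_equal(p$angle_cutoff_small_helical, 45)
  expect_error(classifier_params(slice_width = 7), "integer multiple")
  expect_error(classifier_params(dist_cutoff = -1), "positive")
  expect_silent(classifier_params(slice_width = 7.5))
})

test_that("membrane slicing tiles the slab and bins residues once", {
  fx <- make_helical_bundle(n_units = 5, ring_radius = 10)
  sl <- slice_membrane(fx$protein)
  expect_length(sl, 3)
  expect_equal(vapply(sl, `[[`, 0, "z_min"), c(-15, -5, 5))
  expect_equal(vapply(sl, `[[`, 0, "z_max"), c(-5, 5, 15))

  ca <- lipacc:::ca_coords(fx$protein)
  mem <- rownames(ca)[abs(ca[, 3]) <= 15]
  binned <- unlist(lapply(sl, `[[`, "reskeys"))
  expect_setequal(binned, mem)
  expect_false(any(duplicated(binned)))
  # residues outside the slab are in no slice
  out <- rownames(ca)[abs(ca[, 3]) > 15]
  expect_length(intersect(out, binned), 0)

  sl4 <- slice_membrane(fx$protein, classifier_params(slice_width = 7.5))
  expect_length(sl4, 4)
})

test_that("residues exactly on slice boundaries fall into one slice only", {
  at <- expand.grid(name = c("N", "CA", "C"), resseq = 1:4, stringsAsFactors = FALSE)
  at$chain <- "A"; at$resname <- "ALA"
  at$x <- at$resseq * 4; at$y <- 0
  at$z <- c(-15, -5, 5, 15)[at$resseq] + c(0.3, 0, -0.3)[match(at$name, c("N", "CA", "C"))]
  p <- read_membrane_pdb(tiny_pdb(at))
  sl <- slice_membrane(p)
  expect_identical(sl[[1]]$reskeys, "A:1")           # z = -15 in first slice
  expect_identical(sl[[2]]$reskeys, "A:2")           # z = -5: half-open, slice 2
  expect_identical(sl[[3]]$reskeys, c("A:3", "A:4")) # z = 5 up; z = +15 closed
})

test_that("the sidechain angle reproduces hand-computed planar geometry", {
  mk <- function(cbx, cby) {
    at <- data.frame(name = c("N", "CA", "CB", "C"), resseq = 1, chain = "A",
                     resname = "ALA", x = c(9.5, 10, cbx, 10.5),
                     y = c(-0.5, 0, cby, 0.5), z = 0)
    read_membrane_pdb(tiny_pdb(at))
  }
  expect_equal(sidechain_angle(mk(11, 1), "A:1", c(0, 0)), 135)
  expect_equal(sidechain_angle(mk(11, 0), "A:1", c(0, 0)), 180)
  expect_equal(sidechain_angle(mk(9, 0), "A:1", c(0, 0)), 0)
  # zero-length COM ray: undefined
  expect_true(is.na(sidechain_angle(mk(11, 0), "A:1", c(10, 0))))
})

test_that("pseudo C-beta reconstructs the real C-beta from backbone geometry", {
  fx <- make_single_helix(res_per_unit = 10)
  p <- fx$protein
  for (k in c("A:3", "A:5", "A:8")) {
    real <- lipacc:::atom_coord(p, k, "CB")
    expect_lt(lipacc:::vnorm(pseudo_cbeta(p, k) - real), 0.3)
  }
})

test_that("glycine uses 2HA when present, pseudo C-beta otherwise", {
  at <- data.frame(name = c("N", "CA", "C", "2HA"), resseq = 1, chain = "A",
                   resname = "GLY", x = c(9, 10, 10.5, 12), y = c(0, 0, 1, 2),
                   z = 0)
  p <- read_membrane_pdb(tiny_pdb(at))
  # with 2HA at (12, 2): ray CA->2HA = (2, 2), ray CA->origin = (-1, 0) -> 135
  expect_equal(sidechain_angle(p, "A:1", c(0, 0)), 135)

  p2 <- read_membrane_pdb(tiny_pdb(at[at$name != "2HA", ]))
  expect_true(all(is.finite(pseudo_cbeta(p2, "A:1"))))
  expect_false(is.na(sidechain_angle(p2, "A:1", c(0, 0))))
})

test_that("one or two spans expose the whole membrane region", {
  fx <- make_single_helix()
  fit <- lipid_accessibility(fx$protein, spans = fx$spans)
  ca <- lipacc:::ca_coords(fx$protein)
  mem <- abs(ca[fit$labels$reskey, 3]) <= 15
  expect_true(all(fit$labels$label[mem] == "lipid_exposed"))
  expect_true(all(fit$labels$label[!mem] == "buried"))
  expect_true(all(fit$labels$provenance[mem] == "span_exception"))

  fx2 <- make_helical_bundle(n_units = 2, ring_radius = 9)
  expect_equal(n_spans(fx2$spans), 2)
  fit2 <- lipid_accessibility(fx2$protein, spans = fx2$spans)
  mem2 <- abs(lipacc:::ca_coords(fx2$protein)[fit2$labels$reskey, 3]) <= 15
  expect_true(all(fit2$labels$label[mem2] == "lipid_exposed"))
})

test_that("large bundles bury the core and expose the outer ring by shell membership", {
  bd <- make_helical_bundle(n_units = 9, ring_radius = 12)
  fit <- lipid_accessibility(bd$protein, spans = bd$spans)
  expect_identical(fit$type, "alpha")
  lab <- fit$labels
  central <- lab[grepl("^A:", lab$reskey) & lab$provenance != "outside_membrane", ]
  expect_true(all(central$label == "buried"))
  # outward-facing ring residues (truth exposed) are recovered
  truth <- setNames(bd$truth$label, bd$truth$reskey)
  ring_out <- lab$reskey[!grepl("^A:", lab$reskey) &
                           lab$provenance != "outside_membrane" &
                           truth[lab$reskey] == "lipid_exposed"]
  expect_true(mean(lab$label[match(ring_out, lab$reskey)] == "lipid_exposed") > 0.95)
})

test_that("the beta-barrel angle rule buries lumen-facing shell residues", {
  br <- make_beta_barrel(n_units = 8)
  fit <- lipid_accessibility(br$protein, spans = br$spans)
  expect_identical(fit$type, "beta")
  lab <- fit$labels
  # no residue with angle <= 65 is exposed; all exposures passed the angle
  exposed <- lab$label == "lipid_exposed"
  expect_true(all(lab$angle[exposed] > 65))
  expect_true(all(lab$provenance[exposed] == "angle_pass"))
  expect_true(membrane_agreement(fit, br$truth, br$protein) >= 0.95)
})

test_that("small helical bundles apply the 45-degree pruning rule", {
  b7 <- make_helical_bundle(n_units = 7, ring_radius = 10)
  fit <- lipid_accessibility(b7$protein, spans = b7$spans)
  expect_equal(fit$n_spans, 7)
  lab <- fit$labels
  exposed <- lab$label == "lipid_exposed"
  expect_true(all(lab$angle[exposed] > 45))
  # the angle rule prunes shell calls, it never adds exposures
  expect_true(all(lab$in_shell[exposed]))
})

test_that("exposure requires shell membership whenever spans exceed two", {
  for (fx in list(make_helical_bundle(n_units = 9, ring_radius = 12),
                  make_beta_barrel(n_units = 8))) {
    fit <- lipid_accessibility(fx$protein, spans = fx$spans)
    lab <- fit$labels
    expect_true(all(lab$in_shell[lab$label == "lipid_exposed"]))
  }
})

test_that("classification is deterministic and rotationally invariant", {
  bd <- make_helical_bundle(n_units = 7, ring_radius = 10, noise_sd = 0.3, seed = 5)
  f1 <- lipid_accessibility(bd$protein, spans = bd$spans)
  f2 <- lipid_accessibility(bd$protein, spans = bd$spans)
  expect_identical(f1$labels, f2$labels)

  rotp <- read_membrane_pdb(rotate_pdb_z(bd$pdb, 37))
  f3 <- lipid_accessibility(rotp, spans = bd$spans)
  expect_identical(setNames(f1$labels$label, f1$labels$reskey),
                   setNames(f3$labels$label, f3$labels$reskey))
})

test_that("the exposed set grows monotonically with the shell radius", {
  bd <- make_helical_bundle(n_units = 9, ring_radius = 12)
  prev <- character(0)
  for (r in c(2, 4, 6, 8)) {
    fit <- lipid_accessibility(bd$protein, spans = bd$spans,
                               params = classifier_params(shell_radius = r))
    cur <- fit$labels$reskey[fit$labels$label == "lipid_exposed"]
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("raising the distance cutoff or shrinking the shell reduces exposed calls", {
  n_exposed <- function(fx, ...) {
    fit <- lipid_accessibility(fx$protein, spans = fx$spans,
                               params = classifier_params(...))
    sum(fit$labels$label == "lipid_exposed")
  }
  for (fx in list(make_helical_bundle(n_units = 9, ring_radius = 12),
                  make_beta_barrel(n_units = 10))) {
    expect_lte(n_exposed(fx, dist_cutoff = 15), n_exposed(fx, dist_cutoff = 10))
    expect_lte(n_exposed(fx, shell_radius = 4), n_exposed(fx, shell_radius = 6))
  }
})

test_that("the per-residue report carries one row per residue", {
  fx <- make_beta_barrel(n_units = 8)
  fit <- lipid_accessibility(fx$protein, spans = fx$spans)
  rep <- residue_report(fit)
  expect_equal(nrow(rep), nrow(fx$protein$residues))
  expect_setequal(unique(rep$label), c("lipid_exposed", "buried"))
  f <- withr::local_tempfile(fileext = ".tsv")
  residue_report(fit, file = f)
  expect_equal(nrow(utils::read.delim(f)), nrow(rep))
})
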