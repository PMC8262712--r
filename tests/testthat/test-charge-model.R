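test_that("half-protonation and midpoint identities hold for glycine", {
  toy <- pka_set("toy", n_term = 9, c_term = 2, side_chain = c(D = 4))
  g <- polypeptide("G")
  # at pH = pKa the amino group is half protonated; the carboxyl is ~ -1
  expect_equal(net_charge(g, 9, toy), -0.5, tolerance = 1e-4)
  # midpoint of one acid + one base is the zero-charge point
  expect_equal(net_charge(g, 5.5, toy), 0, tolerance = 1e-6)
  expect_equal(isoelectric_point(polypeptide("GG"), toy, tol = 1e-4), 5.5,
               tolerance = 1e-3)
})

test_that("net charge matches an independent term-by-term summation", {
  emboss <- get_pka_set("EMBOSS")
  for (s in c("KDE", "ACDKRRHYG", "GGG")) {
    qfun <- oracle_charge_fun(s, emboss)
    for (ph in c(0, 2.5, 7, 11, 14)) {
      expect_equal(net_charge(polypeptide(s), ph, emboss), qfun(ph),
                   tolerance = 1e-12)
    }
  }
  expect_error(net_charge(polypeptide("KDE"), 15, emboss), "pH")
})

test_that("registry contains the published sets with valid invariants", {
  reg <- pka_registry()
  expect_gte(length(reg), 17)
  required <- c("EMBOSS", "Dawson", "Rodwell", "Grimsley", "Solomon",
                "Lehninger", "Sillero", "Thurlkill", "Toseland", "Nozaki",
                "Patrickios", "DTASelect", "Wikipedia", "IPC_protein",
                "IPC_peptide", "IPC2_protein", "IPC2_peptide",
                "Bjellqvist", "ProMoST")
  expect_true(all(required %in% names(reg)))
  for (set in reg) {
    vals <- c(set$n_term, set$c_term, set$side_chain)
    expect_true(all(vals > 0 & vals < 14))
  }
  expect_error(get_pka_set("NoSuchSet"), "available")
})

test_that("bisection pI equals the exhaustive grid argmin of |Q|", {
  set.seed(101)
  peps <- random_peptides(20)
  emboss <- get_pka_set("EMBOSS")
  for (p in peps) {
    grid_pi <- oracle_grid_pi(oracle_charge_fun(p$residues, emboss))
    expect_equal(isoelectric_point(p, emboss, tol = 1e-3), grid_pi,
                 tolerance = 2e-3)
  }
})

test_that("charge profiles are strictly decreasing with correct limits", {
  emboss <- get_pka_set("EMBOSS")
  prof <- charge_profile(polypeptide("G"), emboss, step = 0.05)
  expect_true(all(diff(prof$charge) < 0))

  kkk <- charge_profile(polypeptide("KKK"), emboss, step = 0.1)
  expect_equal(kkk$charge[1], 4, tolerance = 1e-2)   # 3 K + N-terminus
  # limits: +basic count at pH 0, -acidic count at pH 14 (within 1e-3 of
  # the group-count bound for groups with pKa away from the boundary)
  set.seed(42)
  for (p in random_peptides(5)) {
    comp <- ionizable_composition(p)
    n_basic <- 1 + sum(comp$counts[c("H", "K", "R")])
    n_acidic <- 1 + sum(comp$counts[c("C", "D", "E", "Y")])
    q <- net_charge(p, c(0, 14), emboss)
    expect_lt(abs(q[1] - n_basic), 0.05)
    # at pH 14 each arginine (pKa 12.5) still carries ~ +0.03
    expect_lt(abs(q[2] + n_acidic), 0.01 + 0.035 * comp$counts[["R"]])
    # profile root bracket matches the bisection pI within one grid step
    prof <- charge_profile(p, emboss, step = 0.01)
    root_at <- prof$pH[which.min(abs(prof$charge))]
    expect_equal(root_at, isoelectric_point(p, emboss, tol = 1e-4),
                 tolerance = 0.01)
  }
})

test_that("monotonicity of Q holds across every registered set", {
  set.seed(7)
  peps <- random_peptides(5)
  grid <- seq(0, 14, by = 0.25)
  for (set in pka_registry()) {
    for (p in peps) {
      q <- net_charge(p, grid, set)
      expect_true(all(diff(q) < 0), info = set$name)
    }
  }
})

test_that("raising any single pKa weakly increases the pI", {
  set.seed(13)
  p <- random_peptides(1, len_range = c(12, 12))[[1]]
  base <- seqpka:::pka_vector(get_pka_set("EMBOSS"))
  pi0 <- isoelectric_point(p, seqpka:::pka_set_from_vector(base), tol = 1e-5)
  for (g in seqpka:::GROUP_ORDER) {
    pert <- base
    pert[g] <- pert[g] + 0.3
    pi1 <- isoelectric_point(p, seqpka:::pka_set_from_vector(pert),
                             tol = 1e-5)
    expect_gte(pi1, pi0 - 1e-4)
  }
  # adding a base raises the root under any valid set
  expect_gt(isoelectric_point(polypeptide("GKG"), "EMBOSS"),
            isoelectric_point(polypeptide("GGG"), "EMBOSS"))
})

test_that("pI of non-positional sets depends only on composition", {
  set.seed(23)
  p <- random_peptides(1, len_range = c(15, 15))[[1]]
  shuffled <- polypeptide(paste(sample(strsplit(p$residues, "")[[1]]),
                                collapse = ""), id = "shuffled")
  for (nm in c("EMBOSS", "IPC_peptide", "Patrickios")) {
    expect_equal(isoelectric_point(p, nm, tol = 1e-5),
                 isoelectric_point(shuffled, nm, tol = 1e-5),
                 tolerance = 1e-4)
  }
  # ...but position-aware sets may differ, and need the sequence
  expect_error(net_charge(ionizable_composition(p), 7,
                          get_pka_set("ProMoST")),
               "position-aware")
})

test_that("vectorized multi-sequence prediction equals the scalar solver", {
  set.seed(31)
  peps <- random_peptides(15)
  for (nm in c("EMBOSS", "Patrickios", "Bjellqvist", "ProMoST")) {
    vec <- predict_pi(peps, nm, tol = 1e-4)
    scl <- vapply(peps, isoelectric_point, numeric(1),
                  set = get_pka_set(nm), tol = 1e-4)
    expect_equal(vec, scl, tolerance = 2e-4)
  }
})

test_that("custom pKa sets load from the documented JSON schema", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sets": {"custom": {"n_term": 9.0, "c_term": 2.1,
    "side_chain": {"D": 3.8, "K": 10.2}}}}', tmp)
  sets <- load_pka_sets(tmp)
  expect_named(sets, "custom")
  expect_equal(sets$custom$side_chain[["K"]], 10.2)
  expect_error(pka_set("bad", 15, 2, c(D = 4)), "0, 14")
  expect_error(pka_set("bad", 9, 2, c(Q = 4)), "unknown side-chain")
})
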