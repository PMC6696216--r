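test_that("condensed Fukui functions match the hand-computed toy oracle", {
  t3 <- toy_triple()
  s <- condensed_fukui(t3$neutral, t3$cation, t3$anion)
  expect_equal(s$f_minus, c(0.5, 0.2, 0.3))
  expect_equal(s$f_plus, c(0.6, 0.2, 0.2))
  expect_equal(sum(s$f_minus), 1)
  expect_equal(sum(s$f_plus), 1)

  s <- dual_descriptor(s)
  expect_equal(s$dual, c(0.1, 0.0, -0.1))
  expect_equal(s$dual_scaled, c(10, 0, -10))
  expect_equal(sum(s$dual), 0)
})

test_that("non-closing or misaligned charge states fail loudly", {
  t3 <- toy_triple()
  # identical charges in all three states: only reachable when a table lies
  # about its net charge, so forge the attribute to hit the closure guard
  fake_cation <- t3$neutral
  attr(fake_cation, "charge_state") <- 1L
  expect_error(condensed_fukui(t3$neutral, fake_cation, t3$anion),
               "do not close", class = "cdft_validation_error")

  permuted <- population_table(c("C", "O", "H"), c(0.4, 0.5, 0.1),
                               charge_state = 1L, multiplicity_hint = 2L)
  expect_error(condensed_fukui(t3$neutral, permuted, t3$anion),
               "element sequence mismatch at atom 1",
               class = "cdft_alignment_error")
  shorter <- population_table(c("O", "C"), c(0.6, 0.4), charge_state = 1L)
  expect_error(condensed_fukui(t3$neutral, shorter, t3$anion),
               class = "cdft_alignment_error")
})

test_that("condensed Fukui is invariant under a uniform charge shift", {
  t3 <- toy_triple()
  base <- condensed_fukui(t3$neutral, t3$cation, t3$anion)
  # shift every atom by 1/n in all three states; net charges shift by +1
  shift <- function(t) population_table(
    t$element, t$mulliken_charge + 1 / nrow(t),
    charge_state = attr(t, "charge_state") + 1L,
    multiplicity_hint = attr(t, "multiplicity_hint"))
  shifted <- condensed_fukui(shift(t3$neutral), shift(t3$cation), shift(t3$anion))
  expect_equal(shifted$f_plus, base$f_plus)
  expect_equal(shifted$f_minus, base$f_minus)
})

test_that("Parr functions pass through radical spin densities", {
  els <- c("O", "C", "H")
  cat <- population_table(els, c(0.5, 0.4, 0.1), spin_density = c(0.7, 0.2, 0.1),
                          charge_state = 1L, multiplicity_hint = 2L)
  an <- population_table(els, c(-0.6, 0.0, -0.4), spin_density = c(0.1, 0.8, 0.1),
                         charge_state = -1L, multiplicity_hint = 2L)
  s <- parr_functions(cat, an)
  expect_equal(s$parr_minus, c(0.7, 0.2, 0.1))
  expect_equal(s$parr_plus, c(0.1, 0.8, 0.1))
  expect_equal(sum(s$parr_minus), 1)

  no_spin <- population_table(els, c(0.5, 0.4, 0.1), charge_state = 1L)
  expect_error(parr_functions(no_spin, an), "spin-density",
               class = "cdft_data_error")
})

test_that("site ranking reproduces the published virotoxin extremes", {
  b <- load_virotoxin_fixtures()
  expected <- list(
    Alaviroidin   = list(nu = c(50L, "C"), el = c(24L, "N")),
    Deoxoviroidin = list(nu = c(1L, "S"), el = c(48L, "C")),
    Deoxoviroisin = list(nu = c(59L, "C"), el = c(49L, "C")),
    Viroidin      = list(nu = c(50L, "C"), el = c(24L, "N")),
    Viroisin      = list(nu = c(1L, "S"), el = c(25L, "N")))
  for (m in names(expected)) {
    r <- rank_sites(b$site_blocks[[m]], mode = "dual")
    expect_identical(as.character(r$nucleophilic$atom_index), expected[[m]]$nu[1])
    expect_identical(r$nucleophilic$element, expected[[m]]$nu[2])
    expect_identical(as.character(r$electrophilic$atom_index), expected[[m]]$el[1])
    expect_identical(r$electrophilic$element, expected[[m]]$el[2])
    # dual and Parr rankings agree, except deoxoviroidin's nucleophilic
    # site: the published block itself puts the larger P+ (0.103) on atom
    # 48 C while the positive dual sits on atom 1 S
    p <- rank_sites(b$site_blocks[[m]], mode = "parr")
    if (m == "Deoxoviroidin")
      expect_identical(p$nucleophilic$atom_index, 48L)
    else
      expect_identical(p$nucleophilic$atom_index, r$nucleophilic$atom_index)
    expect_identical(p$electrophilic$atom_index, r$electrophilic$atom_index)
  }
  # spot-check the published alaviroidin magnitudes
  ala <- b$site_blocks$Alaviroidin
  expect_equal(ala$dual_scaled, c(8.71, -13.59))
  expect_equal(ala$parr_plus[ala$atom_index == 50], 0.227)
  expect_equal(ala$parr_minus[ala$atom_index == 24], 0.275)
})

test_that("rank_sites tie-breaks to the lowest atom index and flags degeneracy", {
  s <- dual_descriptor(site_table(data.frame(
    atom_index = 1:4, element = c("C", "N", "O", "C"),
    f_plus = rep(0.25, 4), f_minus = rep(0.25, 4))))
  r <- rank_sites(s, "dual")
  expect_identical(r$nucleophilic$atom_index, 1L)
  expect_identical(r$electrophilic$atom_index, 1L)
  expect_true(r$degenerate)
  expect_error(rank_sites(s, "parr"), class = "cdft_data_error")
})

test_that("Fukui fields difference congruent grids and integrate to one electron", {
  cb <- make_mock_cubes(mock_spec(seed = 21))
  fm <- fukui_field(cb$rho_n, cb$rho_nm1, kind = "minus")
  fp <- fukui_field(cb$rho_np1, cb$rho_n, kind = "plus")
  expect_equal(attr(fm, "integral"), 1, tolerance = 1e-2)
  expect_equal(attr(fp, "integral"), 1, tolerance = 1e-2)

  z <- fukui_field(cb$rho_n, cb$rho_n, kind = "minus")   # self-difference
  expect_true(all(z$values == 0))
  expect_equal(attr(z, "integral"), 0)

  other <- make_mock_cubes(mock_spec(seed = 21, n_grid = 24))
  expect_error(fukui_field(cb$rho_n, other$rho_n, "minus"),
               "counts", class = "cdft_grid_mismatch")
})

test_that("conservation holds across seeded mock charge-state triples", {
  for (seed in 1:10) {
    logs <- make_mock_log(mock_spec(seed = seed,
                                    n_atoms = 5L + (seed %% 7L)))
    rep <- run_local(logs$neutral, logs$cation, logs$anion)
    expect_equal(unname(rep$sums["f_plus"]), 1, tolerance = 1e-3)
    expect_equal(unname(rep$sums["f_minus"]), 1, tolerance = 1e-3)
    expect_equal(unname(rep$sums["dual"]), 0, tolerance = 2e-3)
  }
})
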