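test_that("gain of function scales or removes tagged deactivation reactions", {
  net <- build_mapk_toy()
  tagged <- vapply(net$reactions, function(rx)
    "deactivation:KRAS" %in% rx$tags, logical(1))
  expect_true(any(tagged))

  # level 1 is the identity
  same <- apply_gof(net, mutation_spec("KRAS", "GoF", 1))
  expect_equal(rate_constants(same), rate_constants(net))

  half <- apply_gof(net, mutation_spec("KRAS", "GoF", 0.5))
  expect_equal(unname(rate_constants(half)[tagged]),
               unname(rate_constants(net)[tagged]) * 0.5)
  expect_equal(unname(rate_constants(half)[!tagged]),
               unname(rate_constants(net)[!tagged]))

  gone <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  expect_identical(length(gone$reactions),
                   length(net$reactions) - sum(tagged))

  expect_error(apply_gof(net, mutation_spec("NOSUCH", "GoF", 0)),
               "MISSING_DEACTIVATION_TAGS")
})

test_that("complete GoF of the GTPase brake overactivates the cascade", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq_phys <- solve_equilibrium(net, basis, x0, seed = 1)
  net_mut <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  eq_mut <- simulate_to_equilibrium(net_mut, x0)  # independent ODE route
  expect_gt(eq_mut$x_e["RasGTP"], eq_phys$x_e["RasGTP"])
  expect_gt(eq_mut$x_e["pp-ERK"], eq_phys$x_e["pp-ERK"])
})

test_that("GTP-bound load is non-increasing in the GoF level", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  ras <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(l) {
    net_l <- apply_gof(net, mutation_spec("KRAS", "GoF", l))
    eq <- solve_equilibrium(net_l, find_conservation_laws(net_l), x0, seed = 1)
    unname(eq$x_e["RasGTP"])
  }, numeric(1))
  expect_true(all(diff(ras) <= 1e-8))
})

test_that("loss of function zeroes the protein and all its compounds", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  x0["PTEN_Pase"] <- 3  # put mass on the complex so the projection matters
  x_lof <- apply_lof(net, x0, mutation_spec("PTEN", "LoF"))
  hit <- c("PTEN", "PTEN_Pase")
  expect_equal(unname(x_lof[hit]), c(0, 0))
  others <- setdiff(names(x0), hit)
  expect_equal(x_lof[others], x0[others])
  expect_error(apply_lof(net, x0, mutation_spec("NOSUCH", "LoF")),
               "UNKNOWN_PROTEIN")
})

test_that("after LoF the zeroed species stay at zero: delta is exactly -1", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq_phys <- solve_equilibrium(net, basis, x0, seed = 1)
  x_lof <- apply_lof(net, x0, mutation_spec("PTEN", "LoF"))
  eq_lof <- solve_equilibrium(net, basis, x_lof, seed = 1)
  prof <- delta_profile(eq_lof$x_e, eq_phys$x_e)
  expect_equal(unname(prof$values[c("PTEN", "PTEN_Pase")]), c(-1, -1))
})

test_that("composed mutations are order-independent", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  gof <- mutation_spec("KRAS", "GoF", 0)
  lof <- mutation_spec("PTEN", "LoF")
  ab <- compose_mutations(net, x0, list(gof, lof))
  ba <- compose_mutations(net, x0, list(lof, gof))
  expect_equal(ab$x0, ba$x0)
  expect_equal(rate_constants(ab$net), rate_constants(ba$net))
  # the resulting equilibria agree too
  eq_ab <- solve_equilibrium(ab$net, find_conservation_laws(ab$net), ab$x0,
                             seed = 1)
  eq_ba <- solve_equilibrium(ba$net, find_conservation_laws(ba$net), ba$x0,
                             seed = 2)
  expect_lt(max(abs(eq_ab$x_e - eq_ba$x_e)) / max(abs(eq_ab$x_e)), 1e-6)

  # empty list is the identity
  id <- compose_mutations(net, x0, list())
  expect_equal(id$x0, x0)
  expect_equal(rate_constants(id$net), rate_constants(net))
  expect_error(compose_mutations(net, x0, list(gof, gof)), "duplicate")
})

test_that("drug augmentation adds the advertised species and reactions", {
  net <- build_mapk_toy()
  spec <- drug_spec("DBF", "competitive", "p-Raf", c0 = 50)
  aug <- add_drug(net, spec)
  expect_identical(length(aug$species), length(net$species) + 2L)
  expect_identical(length(aug$reactions), length(net$reactions) + 2L)
  expect_true(all(c("DBF", "DBF_p-Raf") %in% species_names(aug)))
  x0a <- initial_state(aug)
  expect_equal(unname(x0a["DBF"]), 50)
  expect_equal(unname(x0a["DBF_p-Raf"]), 0)
  # complexes inherit the target composition plus the drug
  cx <- aug$species[[match("DBF_p-Raf", species_names(aug))]]
  expect_setequal(cx$composition, c("DBF", "Raf"))
  tags <- lapply(aug$reactions, `[[`, "tags")
  expect_identical(sum(vapply(tags, function(tg) "drug:DBF" %in% tg,
                              logical(1))), 2L)

  with_deg <- add_drug(net, drug_spec("DBF", "competitive", "p-Raf", c0 = 50,
                                      degradation_rate = dbf_degradation_rate))
  expect_identical(length(with_deg$reactions), length(net$reactions) + 3L)
  deg <- with_deg$reactions[[length(with_deg$reactions)]]
  expect_equal(deg$k, 5.79e-6)
  expect_true("degradation" %in% deg$tags)

  # an allosteric inhibitor binds every listed phosphoform
  tmt <- add_drug(net, drug_spec("TMT", "allosteric",
                                 c("MEK", "p-MEK", "pp-MEK"), c0 = 100))
  expect_identical(length(tmt$species), length(net$species) + 4L)
  expect_identical(length(tmt$reactions), length(net$reactions) + 6L)

  expect_error(add_drug(net, drug_spec("DBF", "competitive", "NOSUCH")),
               "not in network")
  expect_error(add_drug(net, drug_spec("GEF", "competitive", "p-Raf")),
               "collision")
})

test_that("scheduled drugs start at zero and the bolus is an event later", {
  net <- build_mapk_toy()
  spec <- drug_spec("DBF", "competitive", "p-Raf", c0 = 50,
                    schedule_time = 720)
  aug <- add_drug(net, spec)
  expect_equal(unname(initial_state(aug)["DBF"]), 0)
})

test_that("the drug moiety is conserved without degradation, decays with it", {
  net <- build_mapk_toy()
  basis0 <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq <- solve_equilibrium(net, basis0, x0, seed = 1)

  spec <- drug_spec("DBF", "competitive", "p-Raf", c0 = 40)
  aug <- add_drug(net, spec)
  x_init <- extend_state(aug, eq$x_e, spec)
  traj <- simulate_crn(aug, x_init, seq(0, 5000, length.out = 11))
  drug_cols <- c("DBF", "DBF_p-Raf")
  totals <- rowSums(traj$states[, drug_cols])
  expect_equal(totals, rep(40, 11), tolerance = 1e-7)

  spec_deg <- drug_spec("DBF", "competitive", "p-Raf", c0 = 40,
                        degradation_rate = 1e-3)
  aug_deg <- add_drug(net, spec_deg)
  x_init2 <- extend_state(aug_deg, eq$x_e, spec_deg)
  traj2 <- simulate_crn(aug_deg, x_init2, seq(0, 5000, length.out = 11))
  totals2 <- rowSums(traj2$states[, drug_cols])
  expect_true(all(diff(totals2) < 0))
})

test_that("zero dose is inert: the drug-loaded equilibrium is the mutated one", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  net_mut <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  eq_mut <- solve_equilibrium(net_mut, find_conservation_laws(net_mut), x0,
                              seed = 1)
  spec <- drug_spec("DBF", "competitive", "p-Raf", c0 = 0)
  eq_d <- drug_loaded_equilibrium(net_mut, eq_mut$x_e, spec, seed = 1)
  expect_equal(eq_d$x_e[species_names(net_mut)], eq_mut$x_e)
})

test_that("a saturating competitive dose shuts the cascade output down", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  net_mut <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  eq_mut <- solve_equilibrium(net_mut, find_conservation_laws(net_mut), x0,
                              seed = 1)
  spec <- drug_spec("DBF", "competitive", "p-Raf", c0 = 5000)
  eq_d <- drug_loaded_equilibrium(net_mut, eq_mut$x_e, spec,
                                  method = "ode")
  expect_lt(eq_d$x_e["pp-ERK"], 0.01 * eq_mut$x_e["pp-ERK"])
})

test_that("the final drug-loaded equilibrium is schedule-independent", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  net_mut <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  eq_mut <- solve_equilibrium(net_mut, find_conservation_laws(net_mut), x0,
                              seed = 1)
  spec_now <- drug_spec("DBF", "competitive", "p-Raf", c0 = 60)
  spec_late <- drug_spec("DBF", "competitive", "p-Raf", c0 = 60,
                         schedule_time = 720)
  aug <- add_drug(net_mut, spec_now)
  x_now <- extend_state(aug, eq_mut$x_e, spec_now)
  aug_late <- add_drug(net_mut, spec_late)
  x_late <- extend_state(aug_late, eq_mut$x_e, spec_late)
  ev <- administration_event(720, "DBF", 60)
  t_end <- 5e6
  end_now <- simulate_crn(aug, x_now, c(0, t_end))$states[2, ]
  end_late <- simulate_crn(aug_late, x_late, c(0, t_end),
                           events = list(ev))$states[2, ]
  expect_lt(max(abs(end_now - end_late)) / max(end_now), 1e-6)
})
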