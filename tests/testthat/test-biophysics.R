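# Heat-budget solvers: convection, black bulb, endotherm, dehydration.

test_that("sphere convection follows the Ranz-Marshall correlation", {
  # still air: Nu = 2, h = 2 k / d
  expect_equal(convective_coefficient(0.06, 0, Tair_C = 20), 2 * 0.026 / 0.06,
               tolerance = 1e-6)
  h <- convective_coefficient(0.06, seq(0, 10, 0.5))
  expect_true(all(diff(h) > 0))
  expect_equal(convective_coefficient(0.12, 0, 20),
               convective_coefficient(0.06, 0, 20) / 2)
})

test_that("the bulb equilibrates at air temperature in an isothermal cavity", {
  for (tair in c(0, 15, 30, 45)) {
    env <- make_env(Tair = tair, S = 0, wind = 2, Tsky = tair, Tgnd = tair)
    expect_equal(as.numeric(solve_operative_temperature(env)), tair,
                 tolerance = 1e-4)
  }
})

test_that("operative temperature rises monotonically with solar load", {
  te <- vapply(seq(0, 1000, 100), function(s) {
    as.numeric(solve_operative_temperature(make_env(Tair = 30, S = s)))
  }, numeric(1))
  expect_true(all(diff(te) > 0))
})

test_that("the solver matches a 0.01-degC brute-force scan on random environments", {
  envs <- rand_envs(50, seed = 17)
  for (i in seq_len(nrow(envs))) {
    e <- envs[i, , drop = FALSE]
    expect_equal(as.numeric(solve_operative_temperature(e)),
                 brute_force_te(e), tolerance = 0.02 / 30)
  }
})

test_that("non-physical forcing is refused rather than extrapolated", {
  env <- make_env(Tair = 30, S = 5e5)
  expect_error(solve_operative_temperature(env), "non-physical")
})

test_that("bulb output carries the core-conductivity metadata", {
  te <- solve_operative_temperature(make_env())
  expect_equal(attr(te, "params")$core_conductivity_Wm1K1, 0.025)
})

test_that("a mild environment leaves the bird normothermic above basal heat", {
  sp <- default_species("bulbul")
  env <- make_env(Tair = 25, S = 0, wind = 2, Tsky = 5, Tgnd = 25)
  st <- solve_endotherm(env, sp)
  expect_equal(st$Tb_C, sp$Tb_norm_C)
  expect_equal(st$evap_W, sp$baseline_ewl_W)
  expect_gt(st$met_W, sp$basal_met_W)
  expect_false(st$saturated)
  expect_lt(abs(st$balance_residual_W), 1e-3)
})

test_that("an extreme environment saturates at Tb_max with the EWL ceiling", {
  sp <- default_species("bulbul")
  sp$max_ewl_W <- sp$baseline_ewl_W  # no evaporative headroom
  env <- make_env(Tair = 48, S = 1000, wind = 0.5, Tsky = 30, Tgnd = 65)
  st <- solve_endotherm(env, sp)
  expect_true(st$saturated)
  expect_equal(st$Tb_C, sp$Tb_max_C)
  expect_equal(st$evap_W, sp$max_ewl_W)
  expect_gt(st$balance_residual_W, 0)
})

test_that("body temperature ramps monotonically and crosses 42 degC once", {
  sp <- default_species("bulbul")
  tb <- vapply(seq(30, 50, 0.1), function(t) {
    env <- make_env(Tair = t, S = 0, wind = 1, Tsky = t, Tgnd = t)
    solve_endotherm(env, sp, compute_te = FALSE)$Tb_C
  }, numeric(1))
  expect_true(all(diff(tb) > -1e-9))
  expect_equal(sum(diff(tb > 42)), 1L)
  expect_true(all(tb >= sp$Tb_norm_C & tb <= sp$Tb_max_C))
})

test_that("every returned state closes its energy balance", {
  sp_b <- default_species("bulbul")
  sp_h <- default_species("hornbill")
  envs <- rand_envs(150, seed = 23)
  for (i in seq_len(nrow(envs))) {
    for (sp in list(sp_b, sp_h)) {
      st <- solve_endotherm(envs[i, , drop = FALSE], sp, compute_te = FALSE)
      if (!st$saturated) expect_lt(abs(st$balance_residual_W), 1e-3)
    }
  }
})

test_that("tightening the bisection tolerance barely moves Tb", {
  sp <- default_species("bulbul")
  env <- make_env(Tair = 38, S = 600, wind = 1, Tsky = 20, Tgnd = 50)
  t1 <- solve_endotherm(env, sp, tb_tol = 0.01, compute_te = FALSE)$Tb_C
  t2 <- solve_endotherm(env, sp, tb_tol = 0.001, compute_te = FALSE)$Tb_C
  expect_lt(abs(t1 - t2), 0.02)
})

test_that("Te and Tb respond monotonically to each radiative driver", {
  sp <- default_species("bulbul")
  base <- list(Tair = 33, S = 400, Tsky = 13, Tgnd = 45)
  drivers <- list(S = seq(0, 1000, 250), Tsky = seq(0, 33, 8),
                  Tgnd = seq(30, 60, 7.5), Tair = seq(25, 42, 4))
  for (dn in names(drivers)) {
    vals <- drivers[[dn]]
    te <- tb <- numeric(length(vals))
    for (k in seq_along(vals)) {
      a <- base; a[[dn]] <- vals[k]
      env <- make_env(Tair = a$Tair, S = a$S, wind = 1.5,
                      Tsky = a$Tsky, Tgnd = a$Tgnd)
      te[k] <- as.numeric(solve_operative_temperature(env))
      tb[k] <- solve_endotherm(env, sp, compute_te = FALSE)$Tb_C
    }
    expect_true(all(diff(te) > 0), info = paste("Te vs", dn))
    expect_true(all(diff(tb) > -1e-9), info = paste("Tb vs", dn))
  }
})

test_that("the smaller species runs at least as hot in heat", {
  bb <- default_species("bulbul")
  hh <- default_species("hornbill")
  for (s in c(400, 700, 1000)) {
    env <- make_env(Tair = 36, S = s, wind = 1, Tsky = 16, Tgnd = 36 + s / 50)
    tb_b <- solve_endotherm(env, bb, compute_te = FALSE)$Tb_C
    tb_h <- solve_endotherm(env, hh, compute_te = FALSE)$Tb_C
    expect_gte(tb_b, tb_h)
  }
})

test_that("species parameter files round-trip through the YAML reader", {
  sp <- default_species("hornbill")
  expect_s3_class(sp, "species_params")
  expect_equal(sp$mass_g, 200)
  expect_equal(sp$Tb_norm_C, 39.9)
  path <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(sp[setdiff(names(sp), NULL)]), path)
  sp2 <- read_species_params(path)
  expect_equal(sp2[order(names(sp2))], sp[order(names(sp))])
  # allometric default when basal is omitted
  sp3 <- species_params("x", mass_g = 40, Tb_norm_C = 40.4,
                        plumage_depth_m = 0.005, baseline_ewl_W = 0.1,
                        max_ewl_W = 1)
  expect_equal(sp3$basal_met_W, 0.029 * 40^0.72)
  expect_error(species_params("x", 40, 41, Tb_max_C = 40,
                              plumage_depth_m = 0.005,
                              baseline_ewl_W = 0.1, max_ewl_W = 1),
               "Tb_norm")
})

test_that("dehydration timing follows the mass-fraction arithmetic", {
  expect_equal(time_to_dehydration(40, 2.4), 2.5)
  expect_equal(time_to_dehydration(40, 2.4, fraction = 0), 0)
  expect_equal(time_to_dehydration(40, 1.2), 2 * time_to_dehydration(40, 2.4))
  expect_error(time_to_dehydration(40, 0), "positive")
  # rate as a function of Te, constant series: matches the closed form
  rate <- function(te) 0.05 * (te - 40)  # 0.4 g/h at Te = 48
  expect_equal(time_to_dehydration(40, rate, Te_C = 48), 15)
  hrs <- time_to_dehydration(40, rate, Te_C = rep(48, 20), step_h = 1)
  expect_equal(hrs, 15)
  # a series that ends before the limit is an infinite horizon
  expect_equal(time_to_dehydration(40, rate, Te_C = rep(48, 3)), Inf)
  # watts-to-water conversion is the latent-heat constant
  expect_equal(ewl_watts_to_g_per_h(1), 3600 / 2406)
})
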