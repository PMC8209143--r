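test_that("degree-day development accumulates, caps and is exact arithmetic", {
  p <- plant_params(gdd = 100, t_base = 5)
  st <- plant_state(params = p)
  st$season_active <- TRUE
  st <- update_development(st, 5, p)       # at base temperature: no increment
  expect_equal(st$gdd, 0)
  for (inc in c(2, 3, 5)) st <- update_development(st, 5 + inc, p)
  expect_equal(st$dvs, 0.10)               # (2+3+5)/100
  st$gdd <- 100
  st <- update_development(st, 30, p)
  expect_equal(st$dvs, 1)                  # capped
  st <- update_development(st, 30, p)
  expect_equal(st$dvs, 1)
})

test_that("allocation fractions follow the weight shares and sum to one", {
  p <- plant_params(storage = 0.2, root = 1, leaf = 1, stem = 1, cut = 1)
  st <- plant_state(params = p)
  st$dvs <- 0
  th0 <- allocation_fractions(st, p)
  expect_equal(unname(th0[["storage"]]), 0)
  st$dvs <- 0.5
  st$first_cut_done <- TRUE                # gamma_cut = 1
  th <- allocation_fractions(st, p)
  expect_equal(unname(th[["storage"]]), 0.1)
  expect_equal(unname(th[["root"]]), 0.3)
  expect_equal(unname(th[["leaf"]] + th[["stem"]]), 0.6)
  set.seed(5)
  for (i in 1:50) {
    q <- plant_params(storage = runif(1), root = runif(1), leaf = runif(1),
                      stem = runif(1, 0.01), cut = runif(1, 0.1, 1))
    s2 <- plant_state(m = c(storage = runif(1, 0, 500),
                            root = runif(1, 0, 4000),
                            leaf = runif(1, 0, 3000),
                            stem = runif(1, 0, 1500)), params = q)
    s2$dvs <- runif(1)
    s2$first_cut_done <- runif(1) > 0.5
    th <- allocation_fractions(s2, q, assimilate_dm = runif(1, 0, 300))
    expect_equal(sum(th), 1, tolerance = 1e-12)
    expect_true(all(th >= 0))
  }
})

test_that("pre-first-cut multiplier shifts allocation aboveground", {
  p <- plant_params(cut = 0.4)
  st <- plant_state(params = p)
  st$dvs <- 0.3
  before <- allocation_fractions(st, p)
  st$first_cut_done <- TRUE
  after <- allocation_fractions(st, p)
  expect_lt(before[["root"]], after[["root"]])
})

test_that("rubisco limitation factors hit their boundary cases", {
  p <- plant_params()
  st <- plant_state(params = p)
  dry <- rubisco_activity(st, psi = 20, psi_wilt = 22, psi_field = 52,
                          hourly_t = 20, params = p)
  expect_equal(dry$fp_drought, 0)
  expect_equal(dry$a_rubisco, 0)
  warm <- rubisco_activity(st, 52, 22, 52, hourly_t = p$t_limit, params = p)
  expect_equal(warm$fp_temp, 1)            # at and above the critical T
  expect_equal(warm$fp_nitrogen, 1)        # cn at optimum -> ratio 1
  cold <- rubisco_activity(st, 52, 22, 52, hourly_t = 0.8 * p$t_limit,
                           params = p)
  expect_equal(cold$fp_temp, 0)
  mid <- rubisco_activity(st, 52, 22, 52, hourly_t = 0.9 * p$t_limit,
                          params = p)
  expect_equal(mid$fp_temp, 0.5)
  st$cn[["leaf"]] <- p$nc[["leaf"]] / 2
  half_n <- rubisco_activity(st, 52, 22, 52, 20, p)
  expect_equal(half_n$fp_nitrogen, 0.5^p$ndef_leaf)
})

test_that("photosynthesis kernel honours its saturating multiplicative contract", {
  p <- plant_params()
  expect_equal(gross_photosynthesis(5, par = 0, 400, 1, p), 0)
  expect_equal(gross_photosynthesis(0, 300, 400, 1, p), 0)
  g1 <- gross_photosynthesis(5, 300, 400, 1, p)
  expect_equal(gross_photosynthesis(5, 300, 400, 0.5, p), g1 / 2)
  ratio <- gross_photosynthesis(5, 300, 800, 1, p) / g1
  expect_gt(ratio, 1)
  expect_lt(ratio, 2)
  expect_gt(gross_photosynthesis(5, 600, 400, 1, p), g1)
  expect_gt(g1, gross_photosynthesis(2, 300, 400, 1, p))
})

test_that("respiration splits into growth and Q10 maintenance terms", {
  p <- plant_params()
  st <- plant_state(params = p)
  theta <- allocation_fractions(st, p)
  out <- respiration_and_exudation(st, gpp = 100, temp = p$t_ref, theta, p)
  expect_equal(out$rg, p$yield_frac * 100)               # 0.25 * 100 = 25
  expect_equal(unname(out$rm), unname(st$m * p$resp))    # Q10 factor = 1
  expect_equal(out$exudation, p$exudate * out$rg * theta[["root"]])
  st0 <- st
  st0$m[] <- 0
  expect_equal(sum(respiration_and_exudation(st0, 10, 20, theta, p)$rm), 0)
})

test_that("senescence takes the maximum candidate rate per compartment", {
  p <- plant_params(sen_age = 0.002, sen_frost = 0.01, sen_drought = 0.05)
  st <- plant_state(m = c(storage = 100, root = 1000, leaf = 1000,
                          stem = 500), params = p)
  calm <- senescence(st, psi = 52, psi_wilt = 22, psi_field = 52,
                     air_t = 5, soil_t = 5, params = p)
  expect_equal(unname(calm$loss), unname(0.002 * st$m))
  frost <- senescence(st, 52, 22, 52, air_t = -4, soil_t = 2, params = p)
  expect_equal(unname(frost$rates[["frost"]]), 0.04)
  expect_equal(unname(frost$loss[["leaf"]]), 0.04 * 1000)
  expect_equal(unname(frost$loss[["root"]]), 0.002 * 1000)  # soil unfrozen
  # explicit max rule over candidates {drought, frost, age}
  q <- plant_params(sen_age = 0.005, sen_frost = 0.005, sen_drought = 0.02,
                    h2o_sen = 1)
  below_wilt <- senescence(st, 20, 22, 52, air_t = -2, soil_t = -2,
                           params = q)
  expect_equal(unname(below_wilt$loss[["leaf"]]), 0.02 * 1000)
  expect_equal(unname(below_wilt$rates), c(0.02, 0.01, 0.005))
})

test_that("nitrogen demand, uptake and redistribution follow the optima", {
  p <- plant_params(nc = c(storage = 0.01, root = 0.01, leaf = 0.03,
                           stem = 0.02), uptake_max = 1e6)
  st <- plant_state(m = c(storage = 1000, root = 2000, leaf = 3000,
                          stem = 500), params = p)
  st$cn[] <- 0
  out <- redistribute_nitrogen(st, available_mineral_n = 1e6, params = p)
  expect_equal(out$demand, 1000 * 0.01 + 2000 * 0.01 + 3000 * 0.03 +
                 500 * 0.02)               # 130 kg N ha-1 optimum content
  expect_equal(out$uptake, 130)
  expect_equal(unname(out$state$cn), unname(p$nc))
  # dilution: leaf mass doubles while its N amount is fixed, halving the
  # concentration; with no soil N the deficit cannot be refilled
  st2 <- out$state
  st2$m[["leaf"]] <- st2$m[["leaf"]] * 2
  st2$cn[["leaf"]] <- st2$cn[["leaf"]] / 2
  out2 <- redistribute_nitrogen(st2, 0, p)
  expect_lt(out2$state$cn[["leaf"]], p$nc[["leaf"]])
  expect_true(all(out2$state$cn <= p$nc + 1e-12))
  # plant N is conserved through the redistribution
  expect_equal(sum(out2$state$m * out2$state$cn),
               sum(st2$m * st2$cn), tolerance = 1e-9)
})

test_that("cutting harvests above the residuals and relaxes gamma_cut", {
  p <- plant_params()
  st <- plant_state(m = c(storage = 0, root = 2000, leaf = 1500,
                          stem = 900), params = p)
  out <- apply_cut(st, p, residual_leaf = 200, residual_stem = 100)
  expect_equal(out$harvest_dm, 2100)
  expect_equal(out$state$m[["leaf"]], 200)
  expect_equal(out$state$m[["stem"]], 100)
  expect_true(out$state$first_cut_done)
  expect_equal(out$n_exported,
               1300 * st$cn[["leaf"]] + 800 * st$cn[["stem"]])
  # cutting at exactly the residuals harvests nothing
  st2 <- plant_state(m = c(storage = 0, root = 2000, leaf = 200,
                           stem = 100), params = p)
  out2 <- apply_cut(st2, p, 200, 100)
  expect_equal(out2$harvest_dm, 0)
  expect_equal(out2$state$m, st2$m)
})

test_that("cutting translocates the whole storage pool without mass loss", {
  p <- plant_params()
  st <- plant_state(m = c(storage = 500, root = 2000, leaf = 1500,
                          stem = 900), params = p)
  total_before <- sum(st$m)
  out <- apply_cut(st, p, 200, 100)
  expect_equal(out$state$m[["storage"]], 0)
  expect_equal(sum(out$state$m) + out$harvest_dm, total_before,
               tolerance = 1e-9)
})

test_that("season onset and year-end transitions behave as specified", {
  p <- plant_params(t_base = 5)
  st <- plant_state(params = p)
  # threshold zero: active from January 1
  out <- season_transition(st, daily_mean_t = -10, doy = 1,
                           gdd_onset_threshold = 0, params = p)
  expect_true(out$state$season_active)
  # constant 1 degC above base with threshold 100: onset on day 100
  st <- plant_state(params = p)
  onset_day <- NA
  for (doy in 1:150) {
    out <- season_transition(st, daily_mean_t = 6, doy = doy,
                             gdd_onset_threshold = 100, params = p)
    st <- out$state
    if (out$onset_today && is.na(onset_day)) onset_day <- doy
  }
  expect_equal(onset_day, 100)
  # onset moves the storage pool into the other compartments, conserved
  st2 <- plant_state(m = c(storage = 400, root = 2000, leaf = 100,
                           stem = 50), params = p)
  st2$gdd_annual <- 99
  total <- sum(st2$m)
  out2 <- season_transition(st2, 6, doy = 50, gdd_onset_threshold = 100,
                            params = p)
  expect_true(out2$onset_today)
  expect_equal(out2$state$m[["storage"]], 0)
  expect_equal(sum(out2$state$m), total, tolerance = 1e-9)
  # year end resets the seasonal state
  st3 <- out2$state
  st3$dvs <- 0.7
  st3$first_cut_done <- TRUE
  out3 <- season_transition(st3, -5, doy = 1, 100, p)
  expect_equal(out3$state$dvs, 0)
  expect_false(out3$state$first_cut_done)
  expect_false(out3$state$season_active)
})

test_that("the daily plant step matches the naive reference on random inputs", {
  set.seed(11)
  p <- plant_params()
  for (rep in 1:30) {
    m <- c(storage = runif(1, 0, 600), root = runif(1, 100, 4000),
           leaf = runif(1, 0, 3000), stem = runif(1, 0, 1500))
    st <- plant_state(m = m, params = p)
    st$cn <- p$nc * runif(4, 0.4, 1)
    names(st$cn) <- names(p$nc)
    st$dvs <- runif(1)
    st$first_cut_done <- runif(1) > 0.5
    ht <- runif(24, -3, 28)
    hr <- pmax(rnorm(24, 150, 120), 0)
    psi <- runif(1, 20, 55)
    soil_t <- runif(1, -2, 18)
    frost <- -mean(pmax(-ht, 0))
    got <- grasscut:::plant_day_step(st, ht, hr, soil_t, psi, 22, 52, 400,
                                     p, frost)
    want <- ref_plant_day(m, st$cn, st$dvs, st$first_cut_done, ht, hr,
                          soil_t, psi, 22, 52, 400, p, frost)
    expect_equal(got$state$m, want$m, tolerance = 1e-9)
    expect_equal(got$gpp, want$gpp, tolerance = 1e-9)
    expect_equal(got$rm, want$rm, tolerance = 1e-9)
    expect_equal(got$sen_dm, want$sen, tolerance = 1e-9)
    expect_equal(got$state$cn, want$cn, tolerance = 1e-9)
  }
})

test_that("a 30-day coupled trajectory matches the naive reference loop", {
  p <- plant_params()
  m <- c(storage = 300, root = 2500, leaf = 800, stem = 350)
  st <- plant_state(m = m, params = p)
  st$dvs <- 0.2
  ref_m <- m
  ref_cn <- st$cn
  set.seed(99)
  for (day in 1:30) {
    ht <- 12 + 6 * sin(2 * pi * (0:23 - 6) / 24) + rnorm(24, 0, 0.5)
    hr <- pmax(300 * sin(pi * (0:23 - 5) / 14), 0)
    psi <- 52 - day / 3
    frost <- -mean(pmax(-ht, 0))
    got <- grasscut:::plant_day_step(st, ht, hr, soil_t = 10, psi = psi,
                                     psi_wilt = 22, psi_field = 52,
                                     co2 = 400, params = p,
                                     frost_drive = frost)
    st <- got$state
    want <- ref_plant_day(ref_m, ref_cn, st$dvs, st$first_cut_done, ht, hr,
                          10, psi, 22, 52, 400, p, frost)
    ref_m <- want$m
    ref_cn <- want$cn
    expect_equal(st$m, ref_m, tolerance = 1e-9)
  }
})

test_that("plant parameter files load with defaults and validation", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("gdd: 1200", "pmax: 20", "nc:", "  storage: 0.02",
               "  root: 0.012", "  leaf: 0.04", "  stem: 0.015"), path)
  p <- read_plant_params(path)
  expect_equal(p$gdd, 1200)
  expect_equal(p$pmax, 20)
  expect_equal(unname(p$nc[["leaf"]]), 0.04)
  expect_equal(p$sla, plant_params()$sla)     # untouched default
  writeLines("gdd: -5", path)
  expect_error(read_plant_params(path))
  writeLines("not_a_param: 3", path)
  expect_error(read_plant_params(path), "unknown plant parameter")
})
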