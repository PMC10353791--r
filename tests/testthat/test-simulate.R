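test_that("passive response matches the RC closed form within 1%", {
  # 1 uA/cm^2 step onto 0.05 mS/cm^2 leak: 20 mV depolarisation, tau 20 ms
  cfg <- passive_config(g_leak = 0.05, area = 1e-4)
  tr <- simulate_current_clamp(cfg, stimulus_protocol(100), fine_solver)
  vm <- soma_vm(tr)
  expect_equal(tr$vrest, -80, tolerance = 1e-6)
  i_on <- tr$onset_index
  depol <- vm[i_on + round(200 / tr$dt)] - tr$vrest
  expect_equal(depol, 20, tolerance = 0.01)
  # compare the whole charging curve against V(t) = dV (1 - exp(-t/tau))
  tt <- seq(0, 100, by = tr$dt)
  idx <- i_on + round(tt / tr$dt)
  analytic <- tr$vrest + 20 * (1 - exp(-tt / 20))
  expect_lt(max(abs(vm[idx] - analytic)), 0.2)  # 1% of the 20 mV swing
})

test_that("zero-amplitude stimulation stays at the settled rest", {
  for (cfg in list(passive_config(), baselines$gc5, baselines$gc15)) {
    tr <- simulate_current_clamp(cfg, stimulus_protocol(0),
                                 solver_options(dt = 0.05))
    expect_lt(max(abs(soma_vm(tr) - tr$vrest)), 0.5)
  }
})

test_that("dt-halving convergence is monotone; subthreshold traces agree to <0.5 mV", {
  dts <- c(0.1, 0.05, 0.025, 0.0125, 0.00625)
  for (cfg in baselines) {
    vms <- lapply(dts, function(dt)
      soma_vm(simulate_current_clamp(cfg, stimulus_protocol(90),
                                     solver_options(dt = dt))))
    sup <- vapply(1:4, function(i) {
      fine_on_coarse <- vms[[i + 1]][seq(1, length(vms[[i + 1]]), by = 2)]
      max(abs(vms[[i]] - fine_on_coarse))
    }, numeric(1))
    expect_true(all(diff(sup) < 0),
                info = paste("non-monotone convergence:", paste(sup, collapse = " ")))
  }
  # where no spike-time shift is involved the halved-dt agreement is tight
  v1 <- soma_vm(simulate_current_clamp(baselines$gc5, stimulus_protocol(0),
                                       solver_options(dt = 0.05)))
  v2 <- soma_vm(simulate_current_clamp(baselines$gc5, stimulus_protocol(0),
                                       solver_options(dt = 0.025)))
  expect_lt(max(abs(v1 - v2[seq(1, length(v2), by = 2)])), 0.5)
})

test_that("the discrete charge balance holds at every step", {
  cfg <- baselines$gc5
  solver <- solver_options(dt = 0.05)
  tr <- simulate_current_clamp(cfg, stimulus_protocol(90), solver,
                               record_currents = TRUE)
  comp <- vapply(cfg$compartments, `[[`, character(1), "name")
  areas <- vapply(cfg$compartments, `[[`, numeric(1), "area")
  cm <- vapply(cfg$compartments, `[[`, numeric(1), "capacitance") * areas
  gax <- vapply(cfg$compartments, function(cp)
    if (is.na(cp$g_axial)) 0 else cp$g_axial * 1e-3, numeric(1))  # uS -> mS
  parent <- vapply(cfg$compartments, function(cp)
    if (is.na(cp$parent)) NA_integer_ else match(cp$parent, comp), integer(1))
  n <- nrow(tr$vm)
  i_inj <- rep(0, n)
  stim <- seq(tr$onset_index + 1L, tr$onset_index + round(200 / tr$dt))
  i_inj[stim] <- 90 * 1e-6  # pA -> uA
  # per-compartment ionic currents (uA) from the recorded nA series
  ion <- matrix(0, n, length(comp), dimnames = list(NULL, comp))
  for (lbl in colnames(tr$currents)) {
    cn <- sub(".*\\.", "", lbl)
    ion[, cn] <- ion[, cn] + tr$currents[, lbl] * 1e-3
  }
  # axial currents (uA): child -> parent coupling
  ax <- matrix(0, n, length(comp))
  for (i in seq_along(comp)) {
    if (is.na(parent[i])) next
    flow <- gax[i] * (tr$vm[, i] - tr$vm[, parent[i]])
    ax[, i] <- ax[, i] + flow
    ax[, parent[i]] <- ax[, parent[i]] - flow
  }
  rows <- 2:n
  for (i in seq_along(comp)) {
    cap <- cm[i] * diff(tr$vm[, i]) / tr$dt
    inj <- if (comp[i] == "soma") i_inj[rows] else 0
    residual <- cap + ion[rows, i] + ax[rows, i] - inj
    expect_lt(max(abs(residual)), 1e-9)  # uA; machine-level for implicit update
  }
})

test_that("calcium stays non-negative throughout all baseline simulations", {
  for (cfg in baselines) for (amp in c(0, 50, 90)) {
    tr <- simulate_current_clamp(cfg, stimulus_protocol(amp),
                                 solver_options(dt = 0.05))
    expect_true(all(tr$ca >= 0))
  }
})

test_that("current decomposition splits inward and outward contributions", {
  fake_trace <- function(cur) {
    structure(list(dt = 0.1, time = (seq_len(nrow(cur)) - 1) * 0.1,
                   vm = matrix(-70, nrow(cur), 1, dimnames = list(NULL, "soma")),
                   ca = NULL, currents = cur, onset_index = 1L, vrest = -70,
                   protocol = stimulus_protocol(90)),
              class = "voltage_trace")
  }
  cur <- matrix(rep(c(-2, -1, 3), each = 4), nrow = 4,
                dimnames = list(NULL, c("a.soma", "b.soma", "c.soma")))
  d <- decompose_currents(fake_trace(cur))
  expect_equal(unname(d$inward_pct[1, ]), c(200 / 3, 100 / 3, 0))
  expect_equal(unname(d$outward_pct[1, ]), c(0, 0, 100))
  expect_equal(rowSums(d$inward_pct), rep(100, 4))
  # single source carries 100% of its sign class
  d1 <- decompose_currents(fake_trace(cur[, 1, drop = FALSE]))
  expect_equal(unname(d1$inward_pct[, 1]), rep(100, 4))
  expect_true(all(is.na(d1$outward_pct)))
  # an all-zero step is undefined, not numeric
  cur0 <- cur; cur0[2, ] <- 0
  d0 <- decompose_currents(fake_trace(cur0))
  expect_true(all(is.na(d0$inward_pct[2, ])))
  expect_true(all(is.na(d0$outward_pct[2, ])))
  # traces without recorded currents are rejected
  tr <- simulate_current_clamp(baselines$gc5, stimulus_protocol(90),
                               solver_options(dt = 0.1))
  expect_error(decompose_currents(tr), "record_currents")
})

test_that("trace CSV round trip preserves the series", {
  tr <- simulate_current_clamp(baselines$gc5, stimulus_protocol(90),
                               solver_options(dt = 0.1),
                               record_currents = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path, onset_index = tr$onset_index,
                     protocol = tr$protocol)
  expect_equal(back$vm, tr$vm, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$ca, tr$ca, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$dt, tr$dt)
  expect_equal(dim(back$currents), dim(tr$currents))
})
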