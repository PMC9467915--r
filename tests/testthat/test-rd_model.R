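test_that("Stokes-Einstein diffusivity scaling follows absolute temperature", {
  expect_equal(round(stokes_einstein_ratio(22, 55), 2), 1.11)
  expect_equal(stokes_einstein_ratio(37, 37), 1)
  expect_equal(stokes_einstein_ratio(-40, -40), 1)
  expect_equal(stokes_einstein_ratio(37, 55), 328.15 / 310.15)
  expect_error(stokes_einstein_ratio(-300, 20), "absolute zero")
  expect_error(stokes_einstein_ratio(20, -273.15), "absolute zero")
})

test_that("kinetic parameter sets validate and expose the association constant", {
  p <- kinetic_params("x", D_out = 2, k_on = 3, k_off = 6)
  expect_equal(p$D_in_factor, 1 / 7)
  expect_equal(association_constant(p), 0.5)
  expect_error(kinetic_params("x", D_out = 0, k_on = 1, k_off = 1))
  expect_error(kinetic_params("x", D_out = 1, k_on = -1, k_off = 1))
  expect_error(kinetic_params("x", D_out = 1, k_on = 1, k_off = 1,
                              D_in_factor = 2))
  expect_equal(kinetic_params_55c()$k_off, 60.75)
  expect_equal(kinetic_params_55c()$k_on, 2)
  expect_equal(kinetic_params_55c()$D_out, 1.11)
  expect_equal(kinetic_params_55c(elevated_diffusion = FALSE)$D_out, 1)
})

test_that("schedules assign phases over half-open intervals", {
  sch <- two_phase_schedule(kinetic_params_22c(), kinetic_params_55c())
  expect_equal(params_at(sch, 0)$label, "22C")
  expect_equal(params_at(sch, 0.9499)$label, "22C")
  expect_equal(params_at(sch, 0.95)$label, "55C")
  expect_equal(params_at(sch, 1)$label, "55C")
  expect_error(params_at(sch, -0.1), "outside")
  expect_error(params_at(sch, 1.1), "outside")
  single <- rd_schedule(list(list(start = 0, params = kinetic_params_22c())))
  expect_equal(params_at(single, 0.3)$label, "22C")
  expect_error(rd_schedule(list(list(start = 0.2,
                                     params = kinetic_params_22c()))))
  expect_error(two_phase_schedule(kinetic_params_22c(), kinetic_params_55c(),
                                  t_switch = 1.5))
})

test_that("simulation config validates geometry and concentrations", {
  expect_error(sim_config(cylinder_radius = 3))
  expect_error(sim_config(n_r = 2))
  expect_error(sim_config(ab_boundary = -1))
  cfg <- sim_config()
  expect_equal(cfg$n_r, 1000L)
  expect_equal(cfg$n_t, 500L)
})

test_that("no antibody means no reaction and frozen antigen", {
  cfg <- sim_config(n_r = 101, n_t = 11, ab_boundary = 0, ab_init_out = 0)
  sol <- solve_rd(cfg, rd_schedule(list(list(start = 0,
                                             params = kinetic_params_22c()))))
  expect_equal(max(abs(sol$ab)), 0)
  expect_equal(max(abs(sol$ab_ag)), 0)
  expect_equal(sol$ag, matrix(ifelse(sol$inside, 50, 0), 101, 11))
})

test_that("immobile species are conserved and concentrations stay non-negative", {
  cfg <- sim_config(n_r = 201, n_t = 51)
  sch <- two_phase_schedule(kinetic_params_55c(), kinetic_params_22c())
  sol <- solve_rd(cfg, sch)
  ag_init <- ifelse(sol$inside, 50, 0)
  expect_lt(max(abs(sol$ag + sol$ab_ag - ag_init)), 1e-6 * 50)
  expect_gt(min(sol$ab, sol$ag, sol$ab_ag), -1e-8 * 50)
})

test_that("profiles index the stored grid without interpolation", {
  cfg <- sim_config(n_r = 101, n_t = 21)
  sol <- solve_rd(cfg, two_phase_schedule(kinetic_params_55c(),
                                          kinetic_params_22c()))
  p0 <- profile_at(sol, 0, "ab_ag")
  expect_equal(p0$value, rep(0, 101))
  pg <- profile_at(sol, 0, "ag")
  expect_equal(pg$value, ifelse(sol$inside, 50, 0))
  pe <- profile_at(sol, 1, "ab_ag")
  expect_equal(pe$value, sol$ab_ag[, 21])
  # nearest-neighbor in t: 0.024 is closer to t = 0.05 than to t = 0
  pn <- profile_at(sol, 0.026, "ab")
  expect_equal(pn$t_actual, sol$t[2])
  expect_error(profile_at(sol, 2, "ab"), "time range")
  expect_error(profile_at(sol, 0.5, "bogus"))
})

test_that("penetration metrics summarize homogeneity with degenerate guards", {
  mk <- function(v, r = seq(0, 1, length.out = length(v))) {
    structure(list(r = r, value = v, inside = rep(TRUE, length(v)),
                   t_actual = 1, species = "ab_ag"),
              class = "radial_profile")
  }
  m <- penetration_metrics(mk(c(5, 5, 5)))
  expect_equal(m$cv_in, 0)
  expect_equal(m$center_edge_ratio, 1)
  m2 <- penetration_metrics(mk(c(10, 20, 40), r = c(0, 0.5, 1)))
  expect_equal(m2$mean_in, 70 / 3)
  expect_equal(m2$center_edge_ratio, 0.25)
  m3 <- penetration_metrics(mk(c(0, 0, 0)))
  expect_equal(m3$cv_in, 0)
  expect_equal(m3$center_edge_ratio, 1)
  m4 <- penetration_metrics(mk(c(3, 2, 0)))
  expect_equal(m4$center_edge_ratio, Inf)
  expect_error(penetration_metrics(mk(5)))
})

test_that("raising the boundary antibody never lowers bound complex", {
  cfg_for <- function(bv) sim_config(n_r = 81, n_t = 11, ab_boundary = bv,
                                     ab_init_out = bv)
  sch <- rd_schedule(list(list(start = 0, params = kinetic_params_22c())))
  sols <- lapply(c(25, 50, 75), function(bv) solve_rd(cfg_for(bv), sch))
  tol <- 1e-6 * 50
  expect_true(all(sols[[2]]$ab_ag - sols[[1]]$ab_ag >= -tol))
  expect_true(all(sols[[3]]$ab_ag - sols[[2]]$ab_ag >= -tol))
})

test_that("heated kinetics deepen and homogenize staining more than diffusivity", {
  sc <- rd_scenarios(sim_config(n_r = 201, n_t = 51))
  m <- function(nm) sc[sc$scenario == nm, ]
  expect_lt(m("kinetics_only")$cv_in, m("conventional")$cv_in)
  expect_gt(m("kinetics_only")$center_edge_ratio,
            m("conventional")$center_edge_ratio)
  # the diffusivity-only improvement is the smaller effect
  expect_lt(abs(m("diffusion_only")$cv_in - m("conventional")$cv_in),
            abs(m("kinetics_only")$cv_in - m("conventional")$cv_in))
  expect_lt(abs(m("diffusion_only")$center_edge_ratio -
                  m("conventional")$center_edge_ratio),
            abs(m("kinetics_only")$center_edge_ratio -
                  m("conventional")$center_edge_ratio))
})
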