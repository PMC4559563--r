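test_that("supply point puts resources at their stable levels, consumers at zero", {
  sp <- supply_point(fig2a_sys())
  expect_equal(unname(sp$state), c(0, 1))
  expect_true(sp$feasible)
  sp5 <- supply_point(fig5_sys())
  expect_equal(unname(sp5$state), c(0, 0, 1, 1))
  # degenerate zero supply level is still a feasible stationary point
  sys0 <- cr_system(list(resource("R", a = 1, s = 0)),
                    list(consumer("B", 1, growth_holling2(2.5, c(R = 1)), q = c(R = 1))))
  sp0 <- supply_point(sys0)
  expect_equal(unname(sp0$state), c(0, 0))
  expect_true(sp0$feasible)
})

test_that("critical resource levels follow k m / (f_max - m)", {
  mk <- function(f_max, k = 1, m = 1)
    consumer("A", m, growth_holling2(f_max, c(R = k)), q = c(R = 1))
  expect_equal(critical_resource_level(mk(3)), 0.5)
  expect_equal(critical_resource_level(mk(2)), 1)
  expect_equal(critical_resource_level(mk(3, k = 0.7)), 0.35)
  expect_error(critical_resource_level(mk(1)),
               class = "chemocomp_no_positive_solution")
  # liebig branches resolved by resource id
  a5 <- fig5_sys()$consumers$A
  expect_equal(critical_resource_level(a5, "P"), 0.45)
  expect_equal(critical_resource_level(a5, "R"), 0.4)
  expect_error(critical_resource_level(a5), "resource_id")
})

test_that("one-consumer/one-resource coexistence reproduces the worked example", {
  pt <- coexistence_1c1r(fig2a_sys())
  expect_equal(unname(pt$state), c(1 / 3, 2 / 3))
  expect_true(pt$feasible)
  # slow supply, low conversion: identical densities
  pt_c <- coexistence_1c1r(scenario("fig2c")$system)
  expect_equal(pt_c$state, pt$state)
  # stable level below the critical level: consumer density negative, infeasible
  sys_lo <- cr_system(list(resource("R", a = 1, s = 0.5)),
                      list(consumer("B", 1, growth_holling2(2.5, c(R = 1)), q = c(R = 1))))
  pt_lo <- coexistence_1c1r(sys_lo)
  expect_false(pt_lo$feasible)
  expect_lt(pt_lo$state[["B"]], 0)
})

test_that("single-consumer boundary points with one resource match the 2c1r examples", {
  ptB <- single_consumer_point_1r(scenario("fig3b")$system, "B")
  expect_equal(unname(ptB$state), c(0, 0.2, 1))
  ptA <- single_consumer_point_1r(scenario("fig3a")$system, "A")
  expect_equal(unname(ptA$state), c(0.3, 0, 0.5))
  # boundary case s_R = R_A*: zero consumer density, still feasible
  sysb <- cr_system(list(resource("R", a = 1, s = 0.5)),
                    list(consumer("A", 1, growth_holling2(3, c(R = 1)), q = c(R = 1)),
                         consumer("B", 1, growth_holling2(2, c(R = 1)), q = c(R = 1))))
  ptb <- single_consumer_point_1r(sysb, "A")
  expect_equal(ptb$state[["A"]], 0)
  expect_true(ptb$feasible)
})

test_that("single-consumer points with two essential resources pick the consistent branch", {
  s5 <- fig5_sys()
  ptB <- single_consumer_point_2r(s5, "B")
  expect_equal(unname(ptB$state), c(0, 0.5, 0.6, 0.5))
  expect_identical(unname(ptB$limiting), "R")
  ptA <- single_consumer_point_2r(s5, "A")
  expect_equal(unname(ptA$state), c(0.55, 0, 0.45, 0.56))
  expect_identical(unname(ptA$limiting), "P")
  # lower s_R flips consumer A to the R-limited branch
  ptA6 <- single_consumer_point_2r(scenario("fig6a")$system, "A")
  expect_equal(unname(ptA6$state), c(0.5, 0, 0.5, 0.4))
  expect_identical(unname(ptA6$limiting), "R")
  # closed form, not the figure's Euler endpoint: P at the fig6c B-point is 0.4
  ptB6 <- single_consumer_point_2r(scenario("fig6c")$system, "B")
  expect_equal(unname(ptB6$state), c(0, 0.5, 0.4, 0.5))
  # supply point below the isocline: negative consumer density, infeasible
  sys_lo <- scenario("fig4a")$system
  sys_lo$resources$P$s <- 0.3
  sys_lo$resources$R$s <- 0.45
  pt_lo <- single_consumer_point_2r(sys_lo, "B")
  expect_false(pt_lo$feasible)
  expect_lt(pt_lo$state[["B"]], 0)
  # supply line exactly through the isocline corner: flagged
  sys_c <- scenario("fig4a")$system
  sys_c$resources$P$s <- 0.3
  sys_c$resources$R$s <- 0.3
  expect_true(single_consumer_point_2r(sys_c, "B")$on_corner)
})

test_that("two-consumer/two-resource coexistence solves the Q system exactly", {
  pts <- coexistence_2c2r(fig5_sys())
  expect_length(pts, 1)
  pt <- pts[[1]]
  expect_equal(unname(pt$state), c(0.15 / 0.36, 0.06 / 0.36, 0.45, 0.5))
  expect_true(pt$feasible)
  expect_identical(unname(pt$limiting), c("P", "R"))
  expect_lt(max_abs(cr_rhs(fig5_sys(), pt$state)), 1e-9)
  # supply point outside the wedge: a consumer density goes negative
  pts6 <- coexistence_2c2r(scenario("fig6a")$system)
  expect_length(pts6, 1)
  expect_false(pts6[[1]]$feasible)
  # proportional conversion columns: singular Q
  sing <- sys_sing <- fig5_sys()
  sing$consumers$A$q <- c(P = 0.8, R = 1)  # proportional to B's column
  expect_error(coexistence_2c2r(sing), class = "chemocomp_singular_q")
})

test_that("find_all_equilibria enumerates the expected point sets", {
  eq5 <- find_all_equilibria(fig5_sys())
  expect_length(eq5, 4)
  expect_true(all(vapply(eq5, `[[`, logical(1), "feasible")))
  expect_setequal(vapply(eq5, chemocomp:::point_label, character(1)),
                  c("supply", "A-point", "B-point", "coexistence"))
  # a consumer that cannot persist contributes no boundary point
  sys_weak <- cr_system(list(resource("R", a = 1, s = 1)),
                        list(consumer("B", 1, growth_holling2(0.5, c(R = 1)), q = c(R = 1))))
  expect_length(find_all_equilibria(sys_weak), 1)
  # R_A* < s_R < R_B*: B-point exists but is infeasible
  eq3a <- find_all_equilibria(scenario("fig3a")$system)
  feas <- vapply(eq3a, `[[`, logical(1), "feasible")
  labs <- vapply(eq3a, chemocomp:::point_label, character(1))
  expect_true(all(feas[labs %in% c("supply", "A-point")]))
  expect_false(feas[labs == "B-point"])
  # out of closed-form scope
  big <- cr_system(
    list(resource("P", a = 1, s = 1), resource("R", a = 1, s = 1), resource("S", a = 1, s = 1)),
    list(consumer("B", 1, growth_liebig(3, c(P = 1, R = 1, S = 1)), q = c(P = 1, R = 1, S = 1))))
  expect_error(find_all_equilibria(big), class = "chemocomp_unsupported")
})

test_that("with k = m = s = 1 coexistence is feasible exactly above f_max = 2", {
  expect_equal(coexistence_threshold_f_max(1, 1, 1), 2)
  mk <- function(f) cr_system(list(resource("R", a = 1, s = 1)),
                              list(consumer("B", 1, growth_holling2(f, c(R = 1)), q = c(R = 1))))
  expect_true(coexistence_1c1r(mk(2.01))$feasible)
  expect_false(coexistence_1c1r(mk(1.99))$feasible)
  # threshold formula agrees with direct feasibility across random parameters
  set.seed(21)
  for (i in 1:100) {
    m <- runif(1, 0.1, 3); k <- runif(1, 0.1, 3); s <- runif(1, 0.1, 3)
    thr <- coexistence_threshold_f_max(m, k, s)
    sys <- cr_system(list(resource("R", a = 1, s = s)),
                     list(consumer("B", m, growth_holling2(thr * 1.05, c(R = k)), q = c(R = 1))))
    expect_true(coexistence_1c1r(sys)$feasible)
    sys2 <- cr_system(list(resource("R", a = 1, s = s)),
                      list(consumer("B", m, growth_holling2(thr * 0.95, c(R = k)), q = c(R = 1))))
    pt2 <- tryCatch(coexistence_1c1r(sys2),
                    chemocomp_no_positive_solution = function(e) NULL)
    expect_true(is.null(pt2) || !pt2$feasible)
  }
})

test_that("every feasible closed-form equilibrium is a true zero of the dynamics", {
  set.seed(31)
  for (i in 1:250) {
    sys <- sample_system()
    eq <- find_all_equilibria(sys)
    for (p in Filter(function(p) p$feasible, eq))
      expect_lt(max_abs(cr_rhs(sys, p$state)), 1e-9)
  }
})

test_that("coexistence feasibility equals the consumption-vector wedge condition", {
  set.seed(32)
  tried <- 0
  for (i in 1:2000) {
    sys <- sample_system(shape = "2c2r")
    pts <- tryCatch(coexistence_2c2r(sys), error = function(e) list())
    for (p in pts) {
      rstar <- p$state[c("P", "R")]
      s <- vapply(sys$resources, `[[`, numeric(1), "s")
      a <- vapply(sys$resources, `[[`, numeric(1), "a")
      # the wedge statement presumes the supply point above the intersection
      if (any(s <= rstar)) next
      tried <- tried + 1
      Q <- q_matrix(sys)
      ratio <- (a[["P"]] * (s[["P"]] - rstar[["P"]])) /
               (a[["R"]] * (s[["R"]] - rstar[["R"]]))
      rB <- Q["P", "B"] / Q["R", "B"]
      rA <- Q["P", "A"] / Q["R", "A"]
      in_wedge <- if (det(Q) > 0) (rB < ratio && ratio < rA) else (rB > ratio && ratio > rA)
      expect_identical(p$feasible && all(p$state[c("A", "B")] > 0), in_wedge)
    }
  }
  expect_gt(tried, 20)  # the property must actually have been exercised
})
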