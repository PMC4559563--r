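test_that("the Jacobian at the trivial point has the known triangular structure", {
  sys <- fig2a_sys()
  J <- cr_jacobian(sys, c(B = 0, R = 1))
  fB <- holling_growth(1, 2.5, 1)
  expect_equal(unclass(J)[,],
               matrix(c(fB - 1, -fB, 0, -1), 2, 2,
                      dimnames = list(c("B", "R"), c("B", "R"))),
               ignore_attr = TRUE)
  # any state with B = 0 keeps the upper-right entry zero
  set.seed(5)
  for (r in runif(10, 0, 3))
    expect_identical(cr_jacobian(sys, c(B = 0, R = r))["B", "R"], 0)
})

test_that("analytic Jacobians agree with central finite differences at smooth states", {
  set.seed(6)
  for (shape in c("1c1r", "2c1r", "1c2r", "2c2r")) {
    for (i in 1:25) {
      sys <- sample_system(shape = shape)
      x <- rand_smooth_state(sys)
      Ja <- cr_jacobian(sys, x)
      Jf <- cr_jacobian(sys, x, method = "finite_diff")
      expect_lt(max_abs(Ja - Jf) / max(1, max_abs(Ja)), 1e-5)
    }
  }
})

test_that("a Liebig corner state is flagged and handled by the branch convention", {
  sys <- scenario("fig4a")$system  # k_PB = k_RB = 1
  J <- cr_jacobian(sys, c(B = 0.1, P = 0.5, R = 0.5))
  expect_true(attr(J, "on_corner"))
  expect_gt(abs(J["B", "P"]), 0)   # lower-index resource carries the derivative
  expect_identical(J["B", "R"], 0)
})

test_that("closed-form coexistence eigenvalues reproduce the printed pairs", {
  expect_equal(eigen_coexistence_1c1r(fig2a_sys()), c(-0.3 + 0i, -1 + 0i))
  lam <- eigen_coexistence_1c1r(scenario("fig2c")$system)
  expect_equal(Re(lam), c(-0.065, -0.065))
  expect_gt(abs(Im(lam[1])), 0)
  # discriminant-zero boundary: s_R = 16/9 makes the pair collapse at -1
  sysd <- cr_system(list(resource("R", a = 1, s = 16 / 9)),
                    list(consumer("B", 1, growth_holling2(2.5, c(R = 1)), q = c(R = 1))))
  lamd <- eigen_coexistence_1c1r(sysd)
  expect_lt(abs(lamd[1] - lamd[2]), 1e-6)
  expect_equal(Re(lamd), c(-1, -1))
  expect_lt(max_abs(Im(lamd)), 1e-6)
})

test_that("closed-form eigenvalues match the generic eigensolver on random systems", {
  set.seed(8)
  n_done <- 0
  while (n_done < 60) {
    sys <- sample_system(shape = "1c1r")
    pt <- tryCatch(coexistence_1c1r(sys),
                   chemocomp_no_positive_solution = function(e) NULL)
    if (is.null(pt) || !pt$feasible) next
    n_done <- n_done + 1
    lam_closed <- eigen_coexistence_1c1r(sys)
    lam_gen <- classify(sys, pt)$eigenvalues
    expect_lt(max_abs(lam_closed - lam_gen), 1e-9)
  }
})

test_that("classification matches the described stability structure", {
  sys <- fig2a_sys()
  cls_triv <- classify(sys, supply_point(sys))
  expect_identical(cls_triv$class, "saddle")
  expect_equal(cls_triv$eigenvalues, c(0.25 + 0i, -1 + 0i))
  expect_equal(cls_triv$slowest_unstable_rate, 0.25)
  expect_identical(classify(sys, coexistence_1c1r(sys))$class, "stable_node")
  expect_identical(classify(scenario("fig2c")$system,
                            coexistence_1c1r(scenario("fig2c")$system))$class,
                   "stable_vortex")
  # starving consumer: the supply point is a stable node
  sys_weak <- cr_system(list(resource("R", a = 1, s = 1)),
                        list(consumer("B", 1, growth_holling2(0.5, c(R = 1)), q = c(R = 1))))
  expect_identical(classify(sys_weak, supply_point(sys_weak))$class, "stable_node")
  # reversed consumption ratios make the interior point a saddle
  s7 <- scenario("fig7a")$system
  expect_identical(classify(s7, coexistence_2c2r(s7)[[1]])$class, "saddle")
  # near-zero real part is reported as non-hyperbolic, not guessed
  sysb <- cr_system(list(resource("R", a = 1, s = 1)),
                    list(consumer("B", 1, growth_holling2(2, c(R = 1)), q = c(R = 1))))
  expect_identical(classify(sysb, supply_point(sysb))$class, "non_hyperbolic")
})

test_that("the determinant sign criterion reproduces the worked verdicts", {
  s5 <- fig5_sys()
  expect_identical(coexistence_sign_criterion(s5, coexistence_2c2r(s5)[[1]]), "stable")
  s7 <- scenario("fig7a")$system
  expect_identical(coexistence_sign_criterion(s7, coexistence_2c2r(s7)[[1]]), "saddle")
  # identical consumers: gradient determinant vanishes, no verdict
  mk_cons <- function(id) consumer(id, 1, growth_liebig(3, c(P = 0.9, R = 0.8)),
                                   q = c(P = 1, R = 0.8))
  twin_q <- cr_system(list(resource("P", a = 1, s = 1), resource("R", a = 1, s = 1)),
                      list(mk_cons("A"), mk_cons("B")))
  pt <- chemocomp:::new_stationary_point(twin_q, c(0.1, 0.1, 0.45, 0.6), "coexistence",
                                         present = c("A", "B"))
  expect_identical(coexistence_sign_criterion(twin_q, pt), "degenerate")
})

test_that("sign criterion and eigenvalue classification agree on random systems", {
  set.seed(9)
  draws <- sample_feasible_2c2r(120)
  expect_gte(length(draws$systems), 100)
  for (i in seq_along(draws$systems)) {
    sys <- draws$systems[[i]]; pt <- draws$points[[i]]
    verdict <- coexistence_sign_criterion(sys, pt)
    cls <- classify(sys, pt)$class
    if (verdict == "degenerate" || cls == "non_hyperbolic") next
    expect_identical(verdict == "saddle", cls == "saddle")
    if (verdict == "stable") expect_true(cls %in% c("stable_node", "stable_vortex"))
  }
})

test_that("feasible points are only saddles or stable, and a stable point always exists", {
  set.seed(10)
  for (i in 1:150) {
    sys <- sample_system()
    eq <- find_all_equilibria(sys)
    feas <- Filter(function(p) p$feasible, eq)
    classes <- vapply(feas, function(p) classify(sys, p)$class, character(1))
    expect_true(all(classes %in% c("saddle", "stable_node", "stable_vortex",
                                   "non_hyperbolic")))
    expect_false(any(classes %in% c("unstable_node", "unstable_vortex")))
    expect_true(any(classes %in% c("stable_node", "stable_vortex")))
  }
})
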