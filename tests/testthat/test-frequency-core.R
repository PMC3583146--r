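# Equivalence classes, spectra, exact risk metrics and SRSWOR sampling.

test_that("equivalence classes group records by exact value equality", {
  # all identical -> one class
  same <- md_from(age = rep("17", 5), sex = rep("M", 5))
  ec <- build_equivalence_classes(same)
  expect_equal(ec$num_classes, 1L)
  expect_equal(ec$counts, 5L)

  # all distinct -> all singletons
  dist <- md_from(age = as.character(1:5), sex = rep("M", 5))
  ec <- build_equivalence_classes(dist)
  expect_equal(ec$num_classes, 5L)
  expect_true(all(ec$counts == 1L))

  # mixed case, verified against a brute-force pair-counting oracle:
  # each class of size c contributes c*(c-1) ordered matching pairs
  md <- md_from(age = c("17", "17", "17", "17", "17", "18"),
                sex = c("M", "M", "M", "F", "F", "M"))
  ec <- build_equivalence_classes(md)
  expect_setequal(ec$counts, c(3L, 2L, 1L))
  pairs <- 0L
  for (i in seq_len(nrow(md))) for (j in seq_len(nrow(md))) {
    if (i != j && md$age[i] == md$age[j] && md$sex[i] == md$sex[j]) pairs <- pairs + 1L
  }
  expect_equal(sum(ec$counts * (ec$counts - 1L)), pairs)

  expect_error(build_equivalence_classes(md, "height"), "unknown quasi-identifier")
  expect_error(microdata(data.frame(a = character(0))), "at least one record")
})

test_that("spectrum satisfies its conservation identities", {
  sp <- spectrum_of(eq_classes(c(1, 1), keys = c("A", "B")))
  expect_equal(sp$sizes, 1L)
  expect_equal(sp$counts, 2L)
  expect_equal(sp$total, 2L)

  sp <- spectrum_of(c(3, 2, 1, 1))
  expect_equal(sp$sizes, c(1L, 2L, 3L))
  expect_equal(sp$counts, c(2L, 1L, 1L))
  expect_equal(sp$total, 7L)
  expect_equal(sp$num_classes, 4L)

  sp <- spectrum_of(eq_classes(9L, keys = "A"))
  expect_equal(sp$sizes, 9L)
  expect_equal(sp$total, 9L)

  # property: identities hold for random class-size multisets
  for (s in 1:25) {
    sizes <- with_test_seed(s, sample(1:12, sample(1:40, 1), replace = TRUE))
    sp <- spectrum_of(sizes)
    expect_equal(sum(sp$sizes * sp$counts), sum(sizes))
    expect_equal(sum(sp$counts), length(sizes))
    expect_true(all(sp$counts > 0))
  }
})

test_that("lambda metrics reproduce the worked-example configuration", {
  ex <- worked_example()

  # 14-record sample, 9 sample uniques, 2 of them population unique
  expect_equal(ex$small$n, 14L)
  expect_equal(ex$small$sample_uniques, 9L)
  expect_equal(round(ex$small$lambda1, 2), 0.22)
  expect_equal(round(ex$small$lambda2, 2), 0.14)
  expect_equal(ex$small$lambda3, 0.15)
  expect_equal(round(100 * ex$small$naive_rate), 64)

  # 1000-record variant: two records unique in both files
  expect_equal(ex$large$n, 1000L)
  expect_equal(ex$large$lambda1, 1)
  expect_equal(ex$large$lambda2, 0.002)
})

test_that("lambda metrics handle edge and error cases", {
  pop <- eq_classes(c(1, 1, 2, 3), keys = c("a", "b", "c", "d"))
  expect_equal(lambda3(pop), 2 / 7)
  expect_equal(lambda3(eq_classes(rep(1, 5))), 1)
  expect_equal(lambda3(eq_classes(c(2, 3, 4))), 0)

  # sample identical to population: lambda1 = 1, lambda2 = lambda3
  expect_equal(lambda1(pop, pop), 1)
  expect_equal(lambda2(pop, pop), lambda3(pop))

  # no sample uniques: lambda1 undefined, lambda2 = 0
  smp <- eq_classes(c(2, 2), keys = c("c", "d"))
  expect_true(is.na(lambda1(pop, smp)))
  expect_equal(lambda2(pop, smp), 0)

  # containment violations
  stray <- eq_classes(1, keys = "zzz")
  expect_error(lambda1(pop, stray), "containment")
  toobig <- eq_classes(5, keys = "c")  # population class c only has 2
  expect_error(lambda2(pop, toobig), "containment")
})

test_that("lambda2 equals lambda1 times the sample-unique share", {
  for (s in 1:20) {
    pop_md <- as_microdata(generate_crp_population(300, 0.3, 8, seed = s))
    smp <- srswor_sample(pop_md, 0.4, seed = s + 1000)
    pe <- build_equivalence_classes(pop_md)
    se <- build_equivalence_classes(smp)
    l1 <- lambda1(pe, se)
    l2 <- lambda2(pe, se)
    u1 <- sum(se$counts == 1L)
    if (is.na(l1)) {
      expect_equal(l2, 0)
    } else {
      expect_equal(l2, l1 * u1 / se$total)
      expect_lte(l2, l1)
    }
  }
})

test_that("srswor sampling honors its contract", {
  pop <- as_microdata(generate_crp_population(50, 0.2, 3, seed = 5))

  # fraction 1 returns the table unchanged, in order
  expect_identical(as.data.frame(srswor_sample(pop, 1, seed = 1)),
                   as.data.frame(pop))

  # reproducibility: identical seed -> identical sample
  s1 <- srswor_sample(pop, 0.37, seed = 99)
  s2 <- srswor_sample(pop, 0.37, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(nrow(s1), round(0.37 * 50))

  expect_error(srswor_sample(pop, 0, seed = 1), "fraction")
  expect_error(srswor_sample(pop, 1.2, seed = 1), "fraction")

  # sampling never perturbs the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(srswor_sample(pop, 0.5, seed = 7)); b <- runif(1)
  expect_identical(a, b)
})

test_that("mean sample uniques matches the exact hypergeometric expectation", {
  # population of 6 records in classes of sizes [2, 2, 1, 1]; n = 3.
  # Exhaustive oracle: enumerate all C(6,3) = 20 subsets and average the
  # number of sample-unique records in each.
  class_of <- c(1L, 1L, 2L, 2L, 3L, 4L)
  subsets <- utils::combn(6L, 3L)
  oracle <- mean(apply(subsets, 2L, function(idx) {
    tab <- tabulate(class_of[idx], nbins = 4L)
    sum(tab == 1L)
  }))
  # analytic check of the oracle itself: sum_j U_j * j * C(N-j, n-1) / C(N, n)
  sizes <- c(2L, 2L, 1L, 1L)
  analytic <- sum(sizes * choose(6L - sizes, 2L)) / choose(6L, 3L)
  expect_equal(oracle, analytic)

  pop <- md_from(class = as.character(class_of))
  draws <- 50000L
  total_uniques <- 0L
  for (s in seq_len(draws)) {
    smp <- srswor_sample(pop, 0.5, seed = s)
    total_uniques <- total_uniques + sum(table(smp$class) == 1L)
  }
  mc_mean <- total_uniques / draws
  # Monte Carlo standard error: per-draw count has bounded variance <= 2.25
  expect_lt(abs(mc_mean - oracle), 3 * 1.5 / sqrt(draws))
})
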