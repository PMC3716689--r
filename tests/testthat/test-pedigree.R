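test_that("relationship matrix reproduces textbook cases", {
  # unrelated founders
  ped <- pedigree(c("x", "y"), c(NA, NA), c(NA, NA))
  I2 <- diag(2)
  dimnames(I2) <- list(c("x", "y"), c("x", "y"))
  expect_equal(relationship_matrix(ped), I2)
  # trio
  A <- relationship_matrix(ped_trio())
  expect_equal(A["O", "S"], 0.5)
  expect_equal(A["O", "O"], 1)
  # child of a full-sib mating: kinship of full sibs 0.25, F = 0.25
  A2 <- relationship_matrix(ped_fullsib_mating())
  expect_equal(A2["E", "E"], 1.25)
})

test_that("relationship matrix equals twice the transmission-enumeration kinship", {
  peds <- list(
    trio = ped_trio(),
    fullsib = ped_fullsib_mating(),
    halfsib = ped_halfsibs(),
    grandparent = ped_grandparent_loop(),
    random8a = simulate_pedigree(n_founders = 3, n_generations = 2,
                                 offspring_rate = 2, seed = 11),
    random8b = simulate_pedigree(n_founders = 4, n_generations = 1,
                                 offspring_rate = 2, seed = 12))
  for (nm in names(peds)) {
    ped <- peds[[nm]]
    expect_lte(nrow(ped), 8)
    A <- relationship_matrix(ped)
    K <- kinship_enumeration(ped)
    expect_identical(unname(A), unname(2 * K), label = nm)
    # PSD and symmetric
    expect_true(all(eigen(A, symmetric = TRUE, only.values = TRUE)$values >
                      -1e-10))
  }
})

test_that("pedigree validation catches cycles and missing parents", {
  expect_error(pedigree(c("a", "b"), c("b", "a"), c(NA, NA)), "cycle")
  expect_error(pedigree("a", "ghost", NA), "not recorded")
  ped <- pedigree("a", "ghost", NA, add_missing_founders = TRUE)
  expect_setequal(ped$animal, c("a", "ghost"))
  A <- relationship_matrix(ped)
  expect_equal(A["a", "ghost"], 0.5)
})

test_that("pedigree CSV round trip preserves records", {
  ped <- simulate_pedigree(n_founders = 6, n_generations = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_equal(back$animal, ped$animal)
  expect_equal(back$sire, ped$sire)
  expect_equal(back$birth_year, ped$birth_year)
})

test_that("average relationship matches hand-computed values and validates input", {
  A <- relationship_matrix(ped_trio())
  expect_equal(unname(average_relationship(A, "S", c("S", "D", "O"))), 0.5)
  expect_equal(unname(average_relationship(A, "S", "S")), 1)
  # founder unrelated to a population
  ped <- pedigree(letters[1:5], rep(NA, 5), rep(NA, 5))
  Af <- relationship_matrix(ped)
  expect_equal(unname(average_relationship(Af, "a", letters[2:5])), 0)
  expect_error(average_relationship(A, "S", character(0)), "non-empty")
  expect_error(average_relationship(A, "nope", "S"), "nope")
})

test_that("captured diversity solves the relationship system", {
  # 1x1 solve
  r <- captured_diversity(matrix(1, dimnames = list("x", "x")), 0.5)
  expect_equal(unname(r$p), 0.5)
  expect_equal(r$proportion, 0.5)
  # identity system: p = c
  n <- 4
  A <- diag(n); dimnames(A) <- list(letters[1:n], letters[1:n])
  cv <- rep(1 / n, n)
  r2 <- captured_diversity(A, cv)
  expect_equal(unname(r2$p), cv)
  expect_equal(r2$proportion, 1)
  # zero c
  expect_equal(captured_diversity(A, rep(0, n))$proportion, 0)
  # invariance under reordering of the selected set
  ped <- simulate_pedigree(n_founders = 6, n_generations = 2, seed = 3)
  Ap <- relationship_matrix(ped)
  cvec <- average_relationship(Ap, ped$animal, ped$animal)
  ids <- ped$animal[c(2, 5, 9)]
  p1 <- captured_diversity(Ap[ids, ids], cvec[ids])$proportion
  ids2 <- rev(ids)
  p2 <- captured_diversity(Ap[ids2, ids2], cvec[ids2])$proportion
  expect_equal(p1, p2)
})

test_that("near-singular selections fall back to the pseudoinverse with a warning", {
  # a duplicated individual makes A_sub exactly singular
  A <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("u", "u2"), c("u", "u2")))
  expect_warning(r <- captured_diversity(A, c(0.4, 0.4)), "ill-conditioned")
  expect_equal(r$proportion, 0.4, tolerance = 1e-8)
})

test_that("one-animal selection follows the 1x1 closed form of each aggregation", {
  ped <- simulate_pedigree(n_founders = 6, n_generations = 3, seed = 21)
  A <- relationship_matrix(ped)
  cvec <- average_relationship(A, ped$animal, ped$animal)
  # sum aggregation: proportion of a single animal is c / a
  ks <- select_key_animals(ped, m_max = 1)
  closed_sum <- cvec / diag(A)
  expect_equal(ks$selected, names(which.max(closed_sum)))
  expect_equal(unname(ks$cumulative), unname(max(closed_sum)))
  # quadratic aggregation: c^2 / a
  ksq <- select_key_animals(ped, m_max = 1, method = "quadratic")
  closed_q <- cvec^2 / diag(A)
  expect_equal(ksq$selected, names(which.max(closed_q)))
  expect_equal(unname(ksq$cumulative), unname(max(closed_q)))
})

test_that("greedy selection matches brute force where optimal, beats random otherwise", {
  set.seed(99)
  n_eq <- 0; n_tot <- 0
  for (s in 31:40) {
    ped <- simulate_pedigree(n_founders = 4, n_generations = 2,
                             offspring_rate = 2, seed = s)
    A <- relationship_matrix(ped)
    cvec <- average_relationship(A, ped$animal, ped$animal)
    for (m in 1:3) {
      n_tot <- n_tot + 1
      ks <- suppressMessages(select_key_animals(ped, m_max = m))
      greedy <- unname(utils::tail(ks$cumulative, 1))
      best <- best_subset_proportion(A, cvec, m)
      expect_lte(greedy, best$proportion + 1e-9)
      if (abs(greedy - best$proportion) < 1e-9) {
        n_eq <- n_eq + 1
      } else {
        rand <- replicate(25, {
          ss <- sample(ped$animal, m)
          captured_diversity(A[ss, ss, drop = FALSE], cvec[ss])$proportion
        })
        expect_gte(greedy, stats::median(rand))
      }
    }
  }
  expect_gte(n_eq, n_tot / 3)  # optimum reached in a substantial share
})

test_that("cumulative diversity curve is non-decreasing and selection can stop early", {
  ped <- simulate_pedigree(n_founders = 8, n_generations = 3, seed = 7)
  ks <- select_key_animals(ped, m_max = 6)
  expect_true(all(diff(ks$cumulative) >= -1e-12))
  expect_true(all(ks$cumulative >= 0 & ks$cumulative <= 1 + 1e-8))
  # a candidate set unrelated to the population yields no gain
  ped2 <- pedigree(c("p1", "p2", "q1"), c(NA, NA, NA), c(NA, NA, NA))
  expect_message(
    ks2 <- select_key_animals(ped2, population = c("p1", "p2"),
                              candidates = "q1", m_max = 1),
    "no candidate increases")
  expect_length(ks2$selected, 0)
  expect_error(select_key_animals(ped, m_max = 0), "positive")
})
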