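# a deterministic phecode table and subject roster for rule tests
phewas_fixture <- function() {
  subjects <- data.frame(
    subject_id = sprintf("u%03d", 1:40),
    sex = rep(c("male", "female"), 20),
    site = rep(c("site1", "site2"), each = 20),
    birth_decade = rep(c(1940, 1950, 1960, 1970), 10),
    max_age = rep(c(60, 70), 20), stringsAsFactors = FALSE)
  tab <- data.frame(
    subject_id = c("u001", "u002", "u003", "u004", "u005", "u006", "u007"),
    phecode    = c("416", "416", "416", "416.2", "401", "185", "250.2"),
    n_instances = c(3, 2, 1, 4, 2, 2, 1), stringsAsFactors = FALSE)
  list(subjects = subjects, tab = tab, map = read_phecode_map())
}

test_that("case, exclusion and control rules follow the phecode definitions", {
  fx <- phewas_fixture()
  sets <- assemble_case_control(fx$tab, fx$map, fx$subjects, min_cases = 1,
                                case_min_instances = 2, age_match = "none")
  cc <- sets[["416"]]
  # two or more instances -> case; a single instance -> excluded entirely
  expect_setequal(cc$cases, c("u001", "u002"))
  expect_false("u003" %in% cc$controls)
  expect_true("u003" %in% cc$excluded)
  # carrier of the related code 416.2 excluded from controls
  expect_false("u004" %in% cc$controls)
  # unrelated-code carriers remain eligible controls
  expect_true("u005" %in% cc$controls)
  expect_length(intersect(cc$cases, cc$controls), 0)
  # sex-specific code dropped from the scan
  expect_false("185" %in% names(sets))
})

test_that("the minimum case count is enforced as a strict >= threshold", {
  fx <- phewas_fixture()
  n <- 400
  subjects <- data.frame(subject_id = sprintf("v%04d", 1:n),
                         sex = "male", site = "site1", birth_decade = 1950,
                         max_age = 60, stringsAsFactors = FALSE)
  mk <- function(k) data.frame(subject_id = subjects$subject_id[1:k],
                               phecode = "401", n_instances = 2)
  s299 <- assemble_case_control(mk(299), fx$map, subjects, min_cases = 300,
                                age_match = "none")
  expect_false("401" %in% names(s299))
  s300 <- assemble_case_control(mk(300), fx$map, subjects, min_cases = 300,
                                age_match = "none")
  expect_equal(s300[["401"]]$n_case, 300)
})

test_that("controls must fall inside the case birth-decade range", {
  fx <- phewas_fixture()
  # cases only in decades 1940 and 1950
  tab <- data.frame(subject_id = c("u001", "u002"), phecode = "401",
                    n_instances = 2)
  sets <- assemble_case_control(tab, fx$map, fx$subjects, min_cases = 1,
                                age_match = "birth_decade")
  decades <- fx$subjects$birth_decade[match(sets[["401"]]$controls,
                                            fx$subjects$subject_id)]
  expect_true(all(decades >= 1940 & decades <= 1950))
  expect_lt(sets[["401"]]$n_control, 38)
})

test_that("the sensitive cardiomegaly definition nests the standard one", {
  fx <- phewas_fixture()
  strict <- assemble_case_control(fx$tab, fx$map, fx$subjects, min_cases = 1,
                                  case_min_instances = 2,
                                  age_match = "none")[["416"]]
  sensitive <- cardiomegaly_control_set(fx$tab, fx$map, fx$subjects,
                                        age_match = "none")
  # one instance suffices here, so u003 becomes a case
  expect_true("u003" %in% sensitive$cases)
  expect_true(all(strict$cases %in% sensitive$cases))
  expect_gt(sensitive$n_case, strict$n_case)
  # empty table gives an empty result
  empty <- cardiomegaly_control_set(fx$tab[0, ], fx$map, fx$subjects)
  expect_null(empty)
})

test_that("unmapped phecodes warn and skip the related-code exclusion", {
  fx <- phewas_fixture()
  tab <- data.frame(subject_id = c("u001", "u002"), phecode = "999",
                    n_instances = 2)
  expect_warning(
    sets <- assemble_case_control(tab, fx$map, fx$subjects, min_cases = 1,
                                  age_match = "none"),
    "absent from map")
  expect_equal(sets[["999"]]$n_case, 2)
})

test_that("logistic association matches a hand-rolled IRLS oracle", {
  set.seed(101)
  n <- 200
  ids <- sprintf("w%03d", 1:n)
  score <- data.frame(subject_id = ids, raw = rnorm(n),
                      standardized = as.numeric(scale(rnorm(n))))
  class(score) <- c("score_vector", "data.frame")
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 60, 8),
                    row.names = ids)
  lin <- -0.5 + 0.6 * score$standardized + 0.3 * cov$sex
  y <- rbinom(n, 1, plogis(lin))
  subjects <- data.frame(subject_id = ids, site = "site1")
  cc <- structure(list(phecode = "416", cases = ids[y == 1],
                       controls = ids[y == 0], excluded = character(0),
                       n_case = sum(y), n_control = sum(1 - y)),
                  class = "case_control_set")
  row <- logistic_assoc(score, cc, cov, subjects)
  # oracle on the identical design (case rows first, as assembled internally)
  ord <- c(which(y == 1), which(y == 0))
  o <- oracle_irls(y[ord], cbind(score$standardized[ord], cov$sex[ord],
                                 cov$age[ord]))
  expect_equal(row$logor, o$coef[2], tolerance = 1e-6)
  expect_equal(row$se, o$se[2], tolerance = 1e-6)
  expect_true(row$converged)
})

test_that("separated fits are flagged as non-converged", {
  n <- 60
  ids <- sprintf("z%02d", 1:n)
  sv <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  score <- data.frame(subject_id = ids, raw = sv,
                      standardized = as.numeric(scale(sv)))
  class(score) <- c("score_vector", "data.frame")
  y <- as.integer(sv > 0)  # perfect separation
  cc <- structure(list(phecode = "x", cases = ids[y == 1],
                       controls = ids[y == 0], excluded = character(0),
                       n_case = sum(y), n_control = sum(1 - y)),
                  class = "case_control_set")
  subjects <- data.frame(subject_id = ids, site = "site1")
  row <- logistic_assoc(score, cc, NULL, subjects)
  expect_false(row$converged)
  expect_error(meta_fixed_effect(row), "no converged")
})

test_that("fixed-effect meta-analysis matches the closed form and metafor", {
  rows <- data.frame(logor = c(0.1, 0.3), se = c(0.1, 0.1))
  m <- meta_fixed_effect(rows)
  expect_equal(m$logor, 0.2, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / 200), tolerance = 1e-9)
  expect_equal(m$se, 0.0707, tolerance = 1e-3)
  # a single site passes through unchanged
  one <- meta_fixed_effect(data.frame(logor = 0.25, se = 0.07))
  expect_equal(one$logor, 0.25)
  expect_equal(one$se, 0.07)
  # equal SEs pool to the arithmetic mean
  eq <- meta_fixed_effect(data.frame(logor = c(0.1, 0.2, 0.6), se = 0.2))
  expect_equal(eq$logor, mean(c(0.1, 0.2, 0.6)), tolerance = 1e-12)
  skip_if_not_installed("metafor")
  rows2 <- data.frame(logor = c(0.12, -0.05, 0.3), se = c(0.08, 0.15, 0.11))
  m2 <- meta_fixed_effect(rows2)
  mf <- metafor::rma(yi = rows2$logor, sei = rows2$se, method = "FE")
  expect_equal(m2$logor, as.numeric(mf$beta), tolerance = 1e-9)
  expect_equal(m2$se, mf$se, tolerance = 1e-9)
  expect_error(meta_fixed_effect(data.frame(logor = 0.1, se = 0)), "positive")
})

test_that("B-H q-values match the step-up rule and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(102)
  for (i in 1:40) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone in the sorted order
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(!is.unsorted(q[order(p)]))
  expect_equal(significant_at(data.frame(phecode = c("a", "b"),
                                         q = c(0.01, 0.2))), "a")
})

test_that("meta-analysis of homogeneous sites matches the pooled fit", {
  set.seed(103)
  n <- 1200
  ids <- sprintf("h%04d", 1:n)
  sv <- rnorm(n)
  score <- data.frame(subject_id = ids, raw = sv,
                      standardized = as.numeric(scale(sv)))
  class(score) <- c("score_vector", "data.frame")
  y <- rbinom(n, 1, plogis(-1 + 0.4 * sv))
  subjects <- data.frame(subject_id = ids,
                         site = rep(c("site1", "site2", "site3"), length.out = n))
  cc <- structure(list(phecode = "416", cases = ids[y == 1],
                       controls = ids[y == 0], excluded = character(0),
                       n_case = sum(y), n_control = sum(1 - y)),
                  class = "case_control_set")
  rows <- logistic_assoc(score, cc, NULL, subjects)
  m <- meta_fixed_effect(rows)
  pooled <- glm(y ~ sv, family = binomial())
  b <- coef(summary(pooled))["sv", ]
  expect_lt(abs(m$logor - b["Estimate"]), 3 * b["Std. Error"])
})
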