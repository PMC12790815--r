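test_that("causal pairs are exactly the progression edges", {
  g <- toy_graph()
  p <- extract_causal_pairs(g)
  expect_equal(p[, c("from", "to")],
               data.frame(from = c("A01", "B01"), to = c("B01", "C01")))
  expect_equal(nrow(p), sum(g$edges$relation == "progression"))

  g2 <- ckg(data.frame(source = "E119", relation = "is_a", target = "E11"))
  expect_equal(nrow(extract_causal_pairs(g2)), 0)
})

make_cooccurrence_cohort <- function(n, p_a, p_b, both_boost = 0,
                                     a_first_frac = NA, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%05d", seq_len(n))
  a <- rbinom(n, 1, p_a)
  b <- rbinom(n, 1, plogis(qlogis(p_b) + both_boost * a))
  d_a <- as.Date("2005-01-01") + sample(0:1000, n, TRUE)
  if (is.na(a_first_frac)) {
    d_b <- as.Date("2005-01-01") + sample(0:1000, n, TRUE)
  } else {
    first <- runif(n) < a_first_frac
    d_b <- ifelse(first, d_a + 1 + sample(1:100, n, TRUE),
                  d_a - 1 - sample(1:100, n, TRUE))
    d_b <- as.Date(d_b, origin = "1970-01-01")
  }
  dx <- rbind(
    data.frame(person_id = ids[a == 1], icd10 = "D01", date = d_a[a == 1]),
    data.frame(person_id = ids[b == 1], icd10 = "D02", date = d_b[b == 1]))
  cohort(dx,
         data.frame(person_id = character(0), rxnorm = character(0),
                    date = as.Date(character(0))),
         data.frame(person_id = ids))
}

test_that("independent diseases give RR near 1 and no significant pair", {
  coh <- make_cooccurrence_cohort(2000, 0.3, 0.3, seed = 31)
  cp <- compute_comorbidity_pairs(coh, alpha = 0.05)
  expect_equal(nrow(cp$stats), 1)
  expect_lt(abs(cp$stats$rr - 1), 0.2)
  expect_equal(nrow(cp$pairs), 0)
})

test_that("RR formula and one-sided enrichment test match hand computation", {
  coh <- make_cooccurrence_cohort(800, 0.3, 0.25, both_boost = 2, seed = 32)
  cp <- compute_comorbidity_pairs(coh)
  s <- cp$stats
  expect_equal(s$rr, (s$n_both * s$n_total) / (s$n_a * s$n_b))
  tab <- matrix(c(s$n_both, s$n_a - s$n_both, s$n_b - s$n_both,
                  s$n_total - s$n_a - s$n_b + s$n_both), 2, 2)
  expect_equal(s$p_value,
               fisher.test(tab, alternative = "greater")$p.value)
  expect_gt(s$rr, 1)
})

test_that("significant pairs are oriented by the majority first-diagnosis order", {
  coh <- make_cooccurrence_cohort(1500, 0.35, 0.3, both_boost = 2.5,
                                  a_first_frac = 0.9, seed = 33)
  cp <- compute_comorbidity_pairs(coh)
  expect_equal(nrow(cp$pairs), 1)
  expect_equal(cp$pairs$from, "D01")
  expect_equal(cp$pairs$to, "D02")

  # perfect tie in ordering drops the pair
  set.seed(34)
  ids <- sprintf("q%03d", 1:200)
  half <- rep(c(TRUE, FALSE), 100)
  d1 <- as.Date("2005-01-01") + ifelse(half, 0, 10)
  d2 <- as.Date("2005-01-01") + ifelse(half, 10, 0)
  dx <- rbind(data.frame(person_id = ids, icd10 = "D01", date = d1),
              data.frame(person_id = ids, icd10 = "D02", date = d2))
  coh2 <- cohort(dx, data.frame(person_id = character(0),
                                rxnorm = character(0),
                                date = as.Date(character(0))),
                 data.frame(person_id = c(ids, sprintf("r%03d", 1:100))))
  cp2 <- compute_comorbidity_pairs(coh2)
  expect_lt(cp2$stats$q_value, 0.05)
  expect_equal(nrow(cp2$pairs), 0)
})

test_that("null comorbidity screening controls the BH false positive rate", {
  # 12 independent diseases => 66 null pairs, several replicates
  frac_sig <- replicate(5, {
    n <- 600
    ids <- sprintf("p%04d", seq_len(n))
    dx <- do.call(rbind, lapply(1:12, function(k) {
      hit <- rbinom(n, 1, 0.25) == 1
      data.frame(person_id = ids[hit], icd10 = sprintf("N%02d", k),
                 date = as.Date("2005-01-01") + sample(0:999, sum(hit), TRUE))
    }))
    coh <- cohort(dx, data.frame(person_id = character(0),
                                 rxnorm = character(0),
                                 date = as.Date(character(0))),
                  data.frame(person_id = ids))
    cp <- compute_comorbidity_pairs(coh, alpha = 0.05)
    sum(cp$stats$q_value <= 0.05) / nrow(cp$stats)
  })
  se <- sd(frac_sig) / sqrt(length(frac_sig))
  expect_lte(mean(frac_sig), 0.05 + 3 * max(se, 0.01))
})

test_that("hypothesis generation pairs each oriented pair with its indicated drugs", {
  g <- toy_graph()
  pairs <- extract_causal_pairs(g)
  hyp <- generate_hypotheses(pairs, g)
  # A01->B01 has drugs RX1, RX2; B01->C01 has none
  expect_equal(nrow(hyp), 2)
  expect_setequal(hyp$drug, c("RX1", "RX2"))
  expect_true(all(hyp$indication == "A01" & hyp$outcome == "B01"))
  expect_true(all(hyp$status == "candidate"))

  # count identity: sum over pairs of indicated-drug counts
  n_expected <- sum(sapply(pairs$from, function(x)
    sum(g$edges$relation == "indication" & g$edges$target == x)))
  expect_equal(nrow(hyp), n_expected)
})

contradiction_graph <- function() {
  ckg(rbind(
    data.frame(source = "X1", relation = "progression", target = "Y1"),
    data.frame(source = "X2", relation = "progression", target = "Y2"),
    data.frame(source = "X3", relation = "progression", target = "Y3"),
    data.frame(source = "M1", relation = "indication", target = "X1"),
    data.frame(source = "M1", relation = "indication", target = "Y1"),
    data.frame(source = "M2", relation = "indication", target = "X2"),
    data.frame(source = "M3", relation = "indication", target = "X3"),
    data.frame(source = "D9", relation = "side_effect", target = "X2"),
    data.frame(source = "D9", relation = "side_effect", target = "Y2")))
}

test_that("contradiction filter removes exactly the two decoy patterns", {
  g <- contradiction_graph()
  hyp <- generate_hypotheses(extract_causal_pairs(g), g)
  hyp <- filter_contradicted(hyp, g)
  st <- setNames(hyp$status, paste(hyp$indication, hyp$drug, hyp$outcome))
  # M1 indicated for both X1 and Y1 -> rule (i)
  expect_equal(st[["X1 M1 Y1"]], "filtered_contradicted")
  # D9 lists both X2 and Y2 as side effects -> rule (ii)
  expect_equal(st[["X2 M2 Y2"]], "filtered_contradicted")
  expect_equal(st[["X3 M3 Y3"]], "candidate")
})

test_that("contradiction filter survivors equal brute-force predicate evaluation", {
  set.seed(41)
  # random graph: 10 diseases, 6 drugs, random indications/side effects
  dis <- sprintf("D%02d", 1:10)
  drg <- sprintf("M%d", 1:6)
  prog <- data.frame(source = dis[1:5], relation = "progression",
                     target = dis[6:10])
  ind <- unique(data.frame(source = sample(drg, 14, TRUE),
                           relation = "indication",
                           target = sample(dis, 14, TRUE)))
  se <- unique(data.frame(source = sample(drg, 16, TRUE),
                          relation = "side_effect",
                          target = sample(dis, 16, TRUE)))
  g <- ckg(rbind(prog, ind, se))
  hyp <- generate_hypotheses(extract_causal_pairs(g), g)
  out <- filter_contradicted(hyp, g)

  ind_pairs <- paste(ind$source, ind$target)
  se_sets <- split(se$target, se$source)
  for (i in seq_len(nrow(out))) {
    h <- out[i, ]
    rule1 <- paste(h$drug, h$indication) %in% ind_pairs &&
      paste(h$drug, h$outcome) %in% ind_pairs
    rule2 <- any(vapply(se_sets, function(s)
      h$indication %in% s && h$outcome %in% s, TRUE))
    expect_equal(h$status == "filtered_contradicted", rule1 || rule2)
  }
})

test_that("support filter requires the full triple to co-occur in valid order", {
  cfg <- sim_config(n_persons = 300, n_planted = 1, n_null = 0,
                    n_contradicted = 0, n_common_se = 0, n_unsupported = 1)
  sim <- simulate_cohort(cfg, seed = 3)
  hyp <- generate_hypotheses(extract_causal_pairs(sim$graph), sim$graph)
  hyp <- filter_by_support(hyp, sim$cohort, sim$graph)
  st <- setNames(hyp$status, hyp$drug)
  expect_equal(st[["RX001"]], "testable")     # planted, fully supported
  expect_equal(st[["RX002"]], "filtered_support")  # drug never prescribed
})

test_that("the two filters commute", {
  cfg <- sim_config(n_persons = 400, n_planted = 2, n_null = 1,
                    n_contradicted = 1, n_common_se = 1, n_unsupported = 1)
  sim <- simulate_cohort(cfg, seed = 13)
  hyp <- generate_hypotheses(extract_causal_pairs(sim$graph), sim$graph)
  ab <- filter_by_support(filter_contradicted(hyp, sim$graph),
                          sim$cohort, sim$graph)
  ba <- filter_contradicted(filter_by_support(hyp, sim$cohort, sim$graph),
                            sim$graph)
  key <- function(x) paste(x$indication, x$drug, x$outcome)
  expect_setequal(key(ab[ab$status == "testable", ]),
                  key(ba[ba$status == "testable", ]))
  expect_setequal(key(ab[ab$status == "filtered_contradicted", ]),
                  key(ba[ba$status == "filtered_contradicted", ]))
})

test_that("contradiction filter over the N-Triples export matches the native filter", {
  g <- contradiction_graph()
  f <- withr::local_tempfile()
  export_ntriples(g, f)
  g2 <- read_ntriples(f)
  hyp <- generate_hypotheses(extract_causal_pairs(g), g)
  native <- filter_contradicted(hyp, g)
  via_rdf <- filter_contradicted(hyp, g2)
  expect_identical(native$status, via_rdf$status)
})
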