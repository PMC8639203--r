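# Sequential threshold-rule classifiers and their evaluation.

test_that("block construction maps thresholds onto the published structure", {
  blocks <- build_blocks(battery_from_thresholds())
  expect_named(blocks, c("PPPD", "UVH", "CDA"))

  uvh <- blocks$UVH
  expect_equal(uvh$combinator, "any")
  ops <- vapply(uvh$criteria, `[[`, character(1), "op")
  items <- vapply(uvh$criteria, `[[`, character(1), "item")
  expect_equal(items, c("cp_percent", "cus_present"))
  expect_equal(ops, c("ge", "true"))
  expect_equal(uvh$criteria[[1]]$threshold, 19.8)

  cda_age <- blocks$CDA$criteria[[2]]
  expect_equal(cda_age$item, "age")
  expect_equal(cda_age$op, "lt")
  expect_equal(cda_age$threshold, 48.5)

  no_cus <- build_blocks(battery_from_thresholds(), cus_rule = FALSE)
  expect_length(no_cus$UVH$criteria, 1)
  expect_error(build_blocks(battery_from_thresholds()[-1]), "cp_percent")
})

test_that("all six block orderings are enumerated with UD fallback", {
  algs <- enumerate_algorithms(build_blocks(battery_from_thresholds()))
  expect_length(algs, 6)
  first_disease <- vapply(algs, function(a) a$blocks[[1]]$disease,
                          character(1))
  expect_equal(unname(first_disease),
               c("PPPD", "PPPD", "UVH", "UVH", "CDA", "CDA"))
  orders <- lapply(algs, function(a)
    vapply(a$blocks, `[[`, character(1), "disease"))
  expect_equal(length(unique(orders)), 6)   # all permutations distinct
  expect_true(all(vapply(algs, `[[`, character(1), "fallback") == "UD"))

  bad <- build_blocks(battery_from_thresholds())
  bad$UVH <- bad$PPPD
  expect_error(enumerate_algorithms(bad), "exactly one block")
})

test_that("classification is sequential with order-dependent outcomes", {
  algs <- enumerate_algorithms(build_blocks(battery_from_thresholds()))
  rec <- data.frame(age = 50, hads_anxiety = 5, npq_visual = 13,
                    npq_total = 38, cp_percent = 10, cus_present = FALSE)
  expect_equal(classify(rec, algs[["1"]]), "PPPD")   # 38 >= 33.5 fires first

  quiet <- data.frame(age = 60, hads_anxiety = 5, npq_visual = 3,
                      npq_total = 12, cp_percent = 10, cus_present = FALSE)
  for (a in algs) expect_equal(classify(quiet, a), "UD")

  both <- data.frame(age = 60, hads_anxiety = 5, npq_visual = 5,
                     npq_total = 40, cp_percent = 60, cus_present = FALSE)
  expect_equal(classify(both, algs[["1"]]), "PPPD")
  expect_equal(classify(both, algs[["3"]]), "UVH")
})

test_that("the ALL combinator requires every criterion in a block", {
  algs_all <- enumerate_algorithms(
    build_blocks(battery_from_thresholds(), combinator = "all"))
  one_of_two <- data.frame(age = 60, hads_anxiety = 5, npq_visual = 13,
                           npq_total = 12, cp_percent = 10,
                           cus_present = FALSE)
  expect_equal(classify(one_of_two, algs_all[["1"]]), "UD")
  both <- one_of_two; both$npq_total <- 40
  expect_equal(classify(both, algs_all[["1"]]), "PPPD")
})

test_that("missing policies gate classification correctly", {
  algs <- enumerate_algorithms(build_blocks(battery_from_thresholds()))
  rec <- data.frame(age = 50, hads_anxiety = 5, npq_visual = NA,
                    npq_total = 38, cp_percent = 60, cus_present = NA)
  expect_true(is.na(classify(rec, algs[["1"]], "complete_required")))
  expect_equal(classify(rec, algs[["1"]], "missing_negative"), "PPPD")
  # missing CUS never fires, but does not exclude a complete record
  complete <- data.frame(age = 50, hads_anxiety = 5, npq_visual = 3,
                         npq_total = 10, cp_percent = 60, cus_present = NA)
  expect_equal(classify(complete, algs[["1"]], "complete_required"), "UVH")
})

test_that("classification is total and single-positive order-invariant", {
  algs <- enumerate_algorithms(build_blocks(battery_from_thresholds()))
  set.seed(41)
  for (rep in 1:5) {
    co <- random_mini_cohort(60)
    preds <- vapply(algs, function(a) classify(co, a, "missing_negative"),
                    character(60))
    expect_true(all(preds %in% c("PPPD", "CDA", "UVH", "UD")))
    # records positive on exactly one block classify identically everywhere
    blocks <- build_blocks(battery_from_thresholds())
    fires <- vapply(blocks, function(b) vestscreen:::block_fires(co, b),
                    logical(60))
    single <- rowSums(fires) == 1
    if (any(single))
      expect_true(all(apply(preds[single, , drop = FALSE], 1,
                            function(r) length(unique(r)) == 1)))
  }
})

test_that("a disease's recall is maximal when its block is tested first", {
  algs <- enumerate_algorithms(build_blocks(battery_from_thresholds()))
  set.seed(42)
  for (rep in 1:5) {
    co <- random_mini_cohort(80)
    evs <- lapply(algs, function(a) evaluate(co, a, "missing_negative"))
    recalls <- vapply(evs, function(e) e$per_class_recall, numeric(4))
    for (d in c("PPPD", "UVH", "CDA")) {
      first <- vapply(algs, function(a) a$blocks[[1]]$disease == d,
                      logical(1))
      expect_gte(min(recalls[d, first]), max(recalls[d, !first]))
    }
  }
})

test_that("evaluation restricts, counts and aggregates correctly", {
  algs <- enumerate_algorithms(build_blocks(battery_from_thresholds()))
  co <- tiny_cohort()
  ev <- evaluate(co, algs[["1"]], "missing_negative")
  expect_equal(sum(ev$confusion), nrow(co))
  expect_equal(unname(rowSums(ev$confusion)[c("PPPD", "UVH", "CDA", "UD")]),
               c(2, 2, 1, 1))

  # a cohort where every patient fires only its own true block
  clean <- data.frame(
    diagnosis = c("PPPD", "UVH", "CDA", "UD"),
    age = c(60, 70, 30, 60),
    hads_anxiety = c(4, 4, 15, 4),
    npq_visual = c(13, 2, 2, 2), npq_total = c(40, 10, 10, 10),
    cp_percent = c(5, 70, 5, 5),
    cus_present = c(FALSE, TRUE, FALSE, FALSE))
  for (a in algs) {
    ev <- evaluate(clean, a, "missing_negative")
    expect_equal(unname(ev$per_class_recall), rep(100, 4))
    expect_equal(ev$overall_accuracy_excl_ud, 100)
  }

  # UD-true patients never enter the overall-accuracy denominator
  ud_heavy <- clean[rep(4, 10), ]
  ud_heavy$diagnosis <- "UD"
  mixed <- rbind(clean, ud_heavy)
  ev <- evaluate(mixed, algs[["1"]], "missing_negative")
  expect_equal(ev$overall_accuracy_excl_ud, 100)   # UD rows are excluded
})

test_that("overall accuracy aggregation reproduces known identities", {
  n <- c(PPPD = 70, UVH = 14, CDA = 19)
  expect_equal(aggregate_overall(c(PPPD = 56, UVH = 12, CDA = 7), n), 72.8)
  expect_equal(aggregate_overall(c(PPPD = 39, UVH = 13, CDA = 7), n), 57.3)
  expect_equal(aggregate_overall(n, n), 100)
  expect_error(aggregate_overall(c(A = 5), c(A = 4)), "correct <= n")
  expect_error(aggregate_overall(c(UD = 3), c(UD = 10)), "no patients")
})
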