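# A compact imagery run on a tiny grid, already "processed", driven through
# run_feedback with preprocess = FALSE so decoder behavior is fully crafted.
tiny_imagery <- function(seed = 1) {
  sched <- make_imagery_schedule(seed = seed)
  nv <- 8
  run <- volume_series(matrix(0, nv, n_volumes(sched)), c(2L, 2L, 2L), 2)
  list(sched = sched, run = run)
}

oracle_decoder <- function(sched, latency = 2) {
  cond <- tr_conditions(sched)
  function(vol, t) {
    # the display at t shows decode of t - latency; emit the condition that
    # will be on screen when this decode is displayed
    shown <- if (t + latency <= length(cond)) cond[t + latency] else NA
    tap <- !is.na(shown) && shown %in% c("ITAP", "practiceITAP")
    list(decision_value = if (tap) 1 else -1, label = if (tap) "tap" else "rest")
  }
}

test_that("display is driven by the decode two TRs back", {
  fx <- tiny_imagery()
  # decoder alternates tap/rest by acquisition index
  alt <- function(vol, t) {
    tap <- t %% 2 == 0
    list(decision_value = if (tap) 1 else -1, label = if (tap) "tap" else "rest")
  }
  tr <- run_feedback(alt, fx$run, fx$sched, latency_trs = 2, preprocess = FALSE)
  main <- !is.na(tr$condition) & tr$condition %in% c("ITAP", "noITAP")
  expect_true(all(tr$decoded_label[main] ==
                    ifelse((tr$tr_index[main] - 2) %% 2 == 0, "tap", "rest")))
  expect_identical(tr$display[main],
                   ifelse(tr$decoded_label[main] == "tap", "flashing_2hz", "static_cross"))
})

test_that("practice blocks show the ideal pattern and are unscored", {
  fx <- tiny_imagery()
  always_tap <- function(vol, t) list(decision_value = 1, label = "tap")
  tr <- run_feedback(always_tap, fx$run, fx$sched, preprocess = FALSE)
  prac <- tr$condition %in% c("practiceITAP", "practiceNoITAP")
  expect_true(all(tr$outcome[prac] == "unscored"))
  expect_true(all(tr$display[tr$condition %in% "practiceITAP"] == "flashing_2hz"))
  expect_true(all(tr$display[tr$condition %in% "practiceNoITAP"] == "static_cross"))
})

test_that("an oracle decoder scores 100% with only TP/TN outcomes", {
  fx <- tiny_imagery(3)
  tr <- run_feedback(oracle_decoder(fx$sched), fx$run, fx$sched, preprocess = FALSE)
  sc <- score_trace(tr)
  expect_true(all(tr$outcome[tr$outcome != "unscored"] %in% c("TP", "TN")))
  expect_equal(sc$accuracy$overall_acc, 1)
  expect_equal(sc$accuracy$itap_acc, 1)
  expect_equal(sc$accuracy$noitap_acc, 1)
})

test_that("a decoder stuck on tap forces the outcome algebra", {
  fx <- tiny_imagery(4)
  always_tap <- function(vol, t) list(decision_value = 1, label = "tap")
  tr <- run_feedback(always_tap, fx$run, fx$sched, preprocess = FALSE)
  sc <- score_trace(tr)
  expect_equal(sc$accuracy$itap_acc, 1)
  expect_equal(sc$accuracy$noitap_acc, 0)
  itap_share <- sum(tr$condition %in% "ITAP") / sc$counts$n_scored
  expect_equal(sc$accuracy$overall_acc, itap_share)
})

test_that("outcome counts always partition the scored TRs", {
  for (seed in 1:10) {
    fx <- tiny_imagery(seed)
    set.seed(seed)
    noisy <- function(vol, t) {
      tap <- runif(1) > 0.5
      list(decision_value = if (tap) 1 else -1, label = if (tap) "tap" else "rest")
    }
    tr <- run_feedback(noisy, fx$run, fx$sched, preprocess = FALSE)
    sc <- score_trace(tr)
    n_main <- sum(!is.na(tr$condition) & tr$condition %in% c("ITAP", "noITAP"))
    expect_equal(with(sc$counts, tp + fp + tn + fn), n_main)
    expect_equal(sc$counts$n_scored, n_main)
  }
})

test_that("with equal class TR counts overall accuracy is the class mean exactly", {
  # craft a schedule with uniform 30 s blocks so ITAP and noITAP TR counts tie
  conds <- c("practiceITAP", "practiceNoITAP", rep(c("ITAP", "noITAP"), 3))
  b <- data.frame(block_id = seq_along(conds), condition = conds,
                  onset_s = seq(0, by = 30, length.out = 8), duration_s = 30)
  sched <- block_schedule(b, "imagery", tr_s = 2, total_duration_s = 420)
  run <- volume_series(matrix(0, 8, 210), c(2L, 2L, 2L), 2)
  set.seed(2)
  noisy <- function(vol, t) {
    tap <- runif(1) > 0.3
    list(decision_value = if (tap) 1 else -1, label = if (tap) "tap" else "rest")
  }
  tr <- run_feedback(noisy, run, sched, preprocess = FALSE)
  sc <- score_trace(tr)
  expect_equal(sc$accuracy$overall_acc,
               (sc$accuracy$itap_acc + sc$accuracy$noitap_acc) / 2)
})

test_that("score_trace formula arithmetic and degenerate classes", {
  tr <- data.frame(tr_index = 1:120, condition = "ITAP", decision_value = 0,
                   decoded_label = "tap", display = "flashing_2hz",
                   outcome = rep(c("TP", "TN", "FP", "FN"), each = 30))
  sc <- score_trace(tr)
  expect_equal(sc$accuracy$overall_acc, 0.5)
  tr_tp <- transform(tr, outcome = "TP")
  expect_equal(score_trace(tr_tp)$accuracy$itap_acc, 1)
  expect_true(is.na(score_trace(tr_tp)$accuracy$noitap_acc))
})

test_that("feedback replay requires the two practice blocks", {
  sched <- make_tapping_schedule(seed = 1)
  run <- volume_series(matrix(0, 8, 210), c(2L, 2L, 2L), 2)
  expect_error(run_feedback(function(v, t) NULL, run, sched, preprocess = FALSE),
               "practice")
})

test_that("random-label decoding centers overall accuracy on chance", {
  fx <- tiny_imagery(9)
  accs <- sapply(1:40, function(seed) {
    set.seed(seed)
    labs <- sample(c("tap", "rest"), 210, replace = TRUE)
    dec <- function(vol, t) list(decision_value = 0, label = labs[t])
    score_trace(run_feedback(dec, fx$run, fx$sched, preprocess = FALSE))$accuracy$overall_acc
  })
  n_scored <- score_trace(run_feedback(function(v, t)
    list(decision_value = 1, label = "tap"), fx$run, fx$sched,
    preprocess = FALSE))$counts$n_scored
  se <- sqrt(0.25 / (40 * n_scored))
  expect_lt(abs(mean(accs) - 0.5), 4 * se)
})
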