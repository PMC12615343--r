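make_records <- function(df) {
  if (is.null(df$ink_id)) df$ink_id <- sprintf("i%03d", seq_len(nrow(df)))
  if (is.null(df$ink_class)) df$ink_class <- "carbohydrate"
  ink_records(df)
}

test_that("regression recovers exact and null relationships", {
  rec <- make_records(data.frame(n2 = c(0.1, 0.2, 0.3, 0.4),
                                 n1 = c(0.2, 0.4, 0.6, 0.8)))
  r <- pairwise_regression(rec, "n2", "n1")
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_identical(r$transform[["x"]], "identity")
  # independent x and y: r2 stays near zero
  withr::with_seed(13, {
    rec0 <- make_records(data.frame(tan_delta = runif(1000),
                                    dev = runif(1000)))
    expect_lt(pairwise_regression(rec0, "tan_delta", "dev")$r2, 0.02)
  })
  # log-log slope 1 imposed by construction is recovered
  withr::with_seed(14, {
    sy <- 10^runif(50, 1, 4)
    rec1 <- make_records(data.frame(sigma_y = sy,
                                    print_force = 1e-4 * sy *
                                      exp(rnorm(50, 0, 0.05))))
    s <- pairwise_regression(rec1, "sigma_y", "print_force")
    expect_identical(s$transform[["x"]], "log10")
    expect_lt(abs(s$slope - 1), 0.05)
  })
})

test_that("regression failures are informative", {
  rec <- make_records(data.frame(n1 = c(0.1, 0.2), n2 = c(0.1, 0.2)))
  expect_error(pairwise_regression(rec, "n1", "n2"), "insufficient")
  rec2 <- make_records(data.frame(ink_id = c("a", "b", "c"),
                                  sigma_y = c(10, -5, 20),
                                  print_force = c(1, 2, 3)))
  expect_error(pairwise_regression(rec2, "sigma_y", "print_force"), "b")
  rec3 <- make_records(data.frame(n1 = rep(0.3, 5), n2 = 1:5 / 10))
  expect_error(pairwise_regression(rec3, "n2", "n1"), "zero variance")
  # r2 invariant under affine rescaling of an axis (post-transform)
  withr::with_seed(15, {
    rec4 <- make_records(data.frame(n2 = runif(20), dev = runif(20)))
    a <- pairwise_regression(rec4, "n2", "dev")
    rec5 <- rec4; rec5$dev <- 3 * rec5$dev + 0.5
    b <- pairwise_regression(rec5, "n2", "dev")
    expect_equal(a$r2, b$r2, tolerance = 1e-12)
  })
})

test_that("the collapse recovers a known scale ratio of 5", {
  rec <- shifted_collapse_records()
  cl <- collapse_gamma_cr(rec)
  expect_lt(abs(cl$scales[["protein"]] / 5 - 1), 0.15)
  expect_identical(cl$scales[["carbohydrate"]], 1)
  # objective at the recovered scales beats unit scales
  unit <- rheoprint:::.monotone_rss(log10(rec$gamma_cr1), rec$dev)
  expect_lt(cl$objective, unit)
  # characteristic strain of the reference keeps its raw scale
  expect_equal(cl$gamma_char[["carbohydrate"]],
               exp(mean(log(rec$gamma_cr1[rec$ink_class == "carbohydrate"]))))
})

test_that("collapse handles degenerate class structure", {
  one <- make_records(data.frame(gamma_cr1 = 10^runif(8, -3, -1),
                                 dev = runif(8)))
  cl <- collapse_gamma_cr(one)
  expect_identical(unname(cl$scales), 1)
  rec <- shifted_collapse_records()
  rec$ink_class[13:14] <- "fiber"     # fiber left with 2 records
  expect_warning(cl2 <- collapse_gamma_cr(ink_records(as.data.frame(rec))),
                 "excluded")
  expect_false("fiber" %in% cl2$classes_used)
})

test_that("window extraction takes the tan(delta) range of accurate prints", {
  rec <- make_records(data.frame(
    tan_delta = c(0.1, 0.2, 0.3, 0.45, 0.6),
    dev = c(0.5, 0.05, 0.02, 0.08, 0.4)))
  w <- extract_window(rec)
  expect_equal(c(w$tan_delta_low, w$tan_delta_high), c(0.2, 0.45))
  expect_identical(w$n_pass, 3L)
  # a single passer is not a window
  rec1 <- make_records(data.frame(tan_delta = c(0.2, 0.3, 0.4),
                                  dev = c(0.5, 0.05, 0.6)))
  expect_error(extract_window(rec1), "1 ink")
  # tightening the threshold never widens the window
  withr::with_seed(31, {
    rec2 <- make_records(data.frame(tan_delta = runif(50, 0.05, 1),
                                    dev = runif(50, 0, 0.3)))
    thr <- c(0.25, 0.2, 0.15, 0.1)
    ws <- lapply(thr, function(t) extract_window(rec2, dev_threshold = t))
    for (i in seq_len(length(ws) - 1)) {
      expect_gte(ws[[i + 1]]$tan_delta_low, ws[[i]]$tan_delta_low)
      expect_lte(ws[[i + 1]]$tan_delta_high, ws[[i]]$tan_delta_high)
    }
  })
})

test_that("the correlation report reflects generator-imposed structure", {
  co <- generate_cohort(cohort_spec(seed = 11))
  rep <- correlation_report(co)
  pooled <- function(y, x)
    rep[rep$y == y & rep$x == x & rep$subset == "pooled", ]
  expect_gt(pooled("gamma_cr2", "gamma_cr1")$r2, 0.9)
  for (cl in c("carbohydrate", "protein", "fiber")) {
    row <- rep[rep$y == "print_force" & rep$x == "sigma_y" &
                 rep$subset == cl, ]
    expect_gt(row$r2, 0.8)
  }
  # deterministic: same records give the same report
  expect_identical(rep, correlation_report(co))
})

test_that("the report degrades gracefully on degenerate records", {
  rec <- make_records(data.frame(g0 = rep(1000, 4), tan_delta = rep(0.3, 4),
                                 gamma_cr1 = rep(0.01, 4),
                                 gamma_cr2 = rep(0.01, 4),
                                 n1 = rep(0.6, 4), n2 = rep(0.3, 4),
                                 dev = rep(0.1, 4),
                                 print_force = rep(5, 4)))
  rep <- expect_silent(correlation_report(rec))
  expect_true(all(is.na(rep$r2)))
  expect_true(all(grepl("zero variance|insufficient", rep$note)))
})

test_that("ink_records validates the class set and invariants", {
  expect_error(ink_records(data.frame(ink_id = "a", ink_class = "metal")),
               "unknown ink class")
  expect_error(ink_records(data.frame(ink_id = c("a", "a"),
                                      ink_class = "fiber")), "duplicated")
  expect_error(ink_records(data.frame(ink_id = "a", ink_class = "fiber",
                                      dev = -1)), "non-negative")
  r <- ink_records(data.frame(ink_id = "a", ink_class = "fiber",
                              g0 = 100, gamma_cr1 = 0.02))
  expect_equal(r$sigma_y, 2)
})
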