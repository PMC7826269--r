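test_that("a constant trajectory has zero spread", {
  tab <- expand.grid(frame = 1:50, position = 1:3)
  tab$parameter <- "roll"
  tab$value <- 2.5
  s <- summarize_helical(tab)
  expect_true(all(s$sd == 0))
  expect_true(all(s$mean == 2.5))
  expect_true(all(s$n_frames == 50))
})

test_that("large stationary samples concentrate on their moments", {
  set.seed(19)
  n <- 1e5  # one frame every 10 ps over a 1-us trajectory
  tab <- data.frame(frame = seq_len(n), position = 6, parameter = "tilt",
                    value = rnorm(n, mean = 2, sd = 5))
  s <- summarize_helical(tab)
  expect_lt(abs(s$mean - 2), 0.05)
  expect_lt(abs(s$sd - 5), 0.05)
  # subsampling every 10th frame barely moves the mean
  sub <- summarize_helical(tab[tab$frame %% 10 == 0, ])
  expect_lt(abs(sub$mean - s$mean), 3 * 5 / sqrt(n / 10))
})

test_that("summaries equal a direct two-pass computation", {
  set.seed(23)
  tab <- expand.grid(frame = 1:200, position = 6:9)
  tab$parameter <- "buckle"
  tab$value <- rnorm(nrow(tab), sd = 8)
  s <- summarize_helical(tab)
  for (p in 6:9) {
    v <- tab$value[tab$position == p]
    row <- s[s$position == p, ]
    expect_equal(row$mean, mean(v), tolerance = 1e-12)
    expect_equal(row$sd, sd(v), tolerance = 1e-12)
  }
})

test_that("wide-format tables are reshaped, missing cells never imputed", {
  wide <- expand.grid(frame = 1:20, position = 1:2)
  wide$roll <- rnorm(nrow(wide))
  wide$tilt <- rnorm(nrow(wide))
  s <- summarize_helical(wide)
  expect_setequal(unique(s$parameter), c("roll", "tilt"))
  expect_identical(nrow(s), 4L)
  # drop half the frames of position 2: summarized over what is present
  long <- helical_trajectory(wide)
  long <- long[!(long$position == 2 & long$frame > 10), ]
  s2 <- summarize_helical(long)
  expect_identical(s2$n_frames[s2$position == 2 & s2$parameter == "roll"],
                   10L)
})

test_that("difference columns compare against a reference duplex", {
  base <- expand.grid(frame = 1:100, position = 6)
  base$parameter <- "roll"
  set.seed(5)
  base$value <- rnorm(100, mean = 3, sd = 4)
  mod <- base
  mod$value <- rnorm(100, mean = 1, sd = 2)
  s <- summarize_helical(mod, reference = base)
  expect_true(all(c("d_mean", "d_sd") %in% names(s)))
  expect_lt(s$d_mean, 0)  # modified mean is lower by construction
  expect_lt(s$d_sd, 0)    # and narrower
})

test_that("non-finite angles and single frames are rejected", {
  tab <- data.frame(frame = c(1, 2), position = 1, parameter = "roll",
                    value = c(1, NaN))
  expect_error(summarize_helical(tab), "finite")
  one <- data.frame(frame = 1, position = 1, parameter = "roll", value = 1)
  expect_error(summarize_helical(one), "2 frames")
})
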