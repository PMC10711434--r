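test_that("start-frame selection samples only jointly qualifying frames", {
  contacts <- tibble::tibble(
    frame = 0:99,
    Q112 = ifelse(dplyr::between(0:99, 10, 40), 10.25, 8),
    R114 = ifelse(dplyr::between(0:99, 10, 40), 23, 20))
  windows <- list(Q112 = c(10.25, 0.125), R114 = c(23, 0.25))
  sel <- select_start_frames(contacts, windows, n = 20, seed = 3)
  expect_length(sel, 20)
  expect_true(all(sel >= 10 & sel <= 40))
  expect_false(anyDuplicated(sel) > 0)
  # same seed reproduces; different seed differs on a large qualifying set
  expect_identical(sel, select_start_frames(contacts, windows, 20, seed = 3))
  expect_false(identical(sel, select_start_frames(contacts, windows, 20, seed = 4)))
})

test_that("window conditions are joint and failures report the qualifying count", {
  contacts <- tibble::tibble(frame = 0:49, Q112 = 10.25, R114 = 20)
  # Q window satisfied everywhere, R nowhere: joint AND -> zero qualify
  expect_error(
    select_start_frames(contacts,
                        list(Q112 = c(10.25, 0.125), R114 = c(23, 0.25)), 5),
    "only 0 frames")
  expect_error(select_start_frames(contacts, list(), 5), "non-empty")
  expect_error(
    select_start_frames(contacts, list(BAD = c(1, 1)), 5),
    "not a column")
})

test_that("steering input embeds the exact switching literals and endpoints", {
  cx <- synthetic_complex(2, 2, switching = steering_switching())
  spec <- contact_map_spec(
    dplyr::mutate(cx$spec$pairs,
                  donor_eleno = dplyr::row_number(),
                  acceptor_eleno = dplyr::row_number() + 100L),
    steering_switching())
  sched <- steering_schedule(lambda_map(108, 65), duration_ns = 100,
                             force_constant = 500, n_runs = 20)
  txt <- emit_steering_input(spec, sched)
  joined <- paste(txt, collapse = "\n")
  expect_match(joined, "R_0=3.0 D_0=0.3 NN=1 MM=12", fixed = TRUE)
  expect_match(joined, "AT0=108.0", fixed = TRUE)
  expect_match(joined, "AT1=65.0", fixed = TRUE)
  expect_match(joined, "STEP1=50000000", fixed = TRUE)  # 100 ns at 2 fs
  # byte-identical across invocations
  expect_identical(txt, emit_steering_input(spec, sched))
  expect_error(emit_steering_input(spec, sched, dialect = "colvars"),
               "unsupported")
  expect_error(emit_steering_input(cx$spec, sched), "serials")
})

test_that("work accumulation obeys its closed forms", {
  m <- lambda_map(10, 0)
  sched <- steering_schedule(m, duration_ns = 1, force_constant = 2)
  t <- seq(0, 1000, length.out = 501)
  center <- seq(10, 0, length.out = 501)
  # perfect tracking: zero lag, zero work
  w0 <- accumulate_work(tibble::tibble(time_ps = t, cv = center, center = center), sched)
  expect_equal(w0$work, rep(0, 501))
  expect_equal(w0$lambda[1], 1)
  # constant lag delta: w = k * delta * D (telescoping sum)
  delta <- 0.7
  wl <- accumulate_work(tibble::tibble(time_ps = t, cv = center + delta,
                                       center = center), sched)
  expect_equal(wl$work[501], 2 * delta * 10, tolerance = 1e-9)
  # frozen cv at c_start: Riemann sum of k (c - c_start) dc -> k D^2 / 2
  wf <- accumulate_work(tibble::tibble(time_ps = t, cv = 10, center = center), sched)
  exact <- 2 * 10^2 / 2
  expect_equal(wf$work[501], exact, tolerance = 1e-2 * exact)
  # against a 100x finer numeric integral
  tf <- seq(0, 1000, length.out = 50001)
  cf <- seq(10, 0, length.out = 50001)
  wff <- accumulate_work(tibble::tibble(time_ps = tf, cv = 10, center = cf), sched)
  expect_equal(wf$work[501], wff$work[50001], tolerance = 2e-2)
})

test_that("work accumulation is additive over contiguous segments", {
  m <- lambda_map(5, 1)
  sched <- steering_schedule(m, 1, 3)
  withr::with_seed(8, {
    t <- seq(0, 100, length.out = 201)
    center <- seq(5, 1, length.out = 201)
    cv <- center + rnorm(201, 0, 0.2)
  })
  full <- accumulate_work(tibble::tibble(time_ps = t, cv = cv, center = center), sched)
  first <- accumulate_work(tibble::tibble(time_ps = t[1:101], cv = cv[1:101],
                                          center = center[1:101]), sched)
  second <- accumulate_work(tibble::tibble(time_ps = t[101:201], cv = cv[101:201],
                                           center = center[101:201]), sched)
  expect_equal(full$work[201], first$work[101] + second$work[101], tolerance = 1e-12)
  # time-reversal of a perfectly tracked pull does zero work either way
  perfect <- tibble::tibble(time_ps = t, cv = center, center = center)
  fw <- accumulate_work(perfect, sched)
  bw <- accumulate_work(
    tibble::tibble(time_ps = t, cv = rev(center), center = rev(center)),
    sched, monotone = FALSE)
  expect_equal(max(abs(fw$work)), 0)
  expect_equal(max(abs(bw$work)), 0)
})

test_that("direction violations and bad series are rejected", {
  sched <- steering_schedule(lambda_map(5, 1), 1, 3)
  up <- tibble::tibble(time_ps = 0:10, cv = 1, center = seq(1, 5, length.out = 11))
  expect_error(accumulate_work(up, sched), "non-increasing")
  short <- tibble::tibble(time_ps = 0, cv = 1, center = 5)
  expect_error(accumulate_work(short, sched), "too short")
})

test_that("COLVAR files round-trip and reject malformed content", {
  df <- tibble::tibble(time_ps = c(0, 1, 2), cv = c(5, 4, 3),
                       center = c(5, 4, 3), work = c(0, 0.1, 0.3))
  path <- withr::local_tempfile(fileext = ".colvar")
  write_colvar(df, path, header = "provenance: test")
  back <- read_colvar(path)
  expect_equal(back, df)
  writeLines(c("1 2 3"), path)
  expect_error(read_colvar(path), "FIELDS")
  writeLines(c("#! FIELDS time cv"), path)
  expect_error(read_colvar(path), "no data rows")
})
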