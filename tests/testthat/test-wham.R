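test_that("the harmonic bias follows its quadratic form", {
  expect_equal(bias_potential(21, 20, 5), 2.5)
  expect_equal(bias_potential(20, 20, 5), 0)
  expect_equal(bias_potential(22, 20, 5), 4 * bias_potential(21, 20, 5))
})

test_that("a single effectively unbiased window yields a flat PMF and
           the histogram limit", {
  set.seed(2)
  samples <- runif(20000, 10, 12)
  w <- umbrella_window(11, 1e-9, samples)
  prof <- wham(list(w), bin_width = 0.25)
  inner <- prof$free_energy[prof$xi > 10.3 & prof$xi < 11.7]
  expect_lt(max(inner) - min(inner), 0.05)

  # offset-free limit: PMF = -kT log(histogram), anchored
  h <- prof$count / sum(prof$count)
  ref <- -0.0019872041 * 300 * log(h)
  ref <- ref - min(ref)
  expect_equal(prof$free_energy, ref, tolerance = 1e-6)
})

test_that("unbiased probability normalizes before the log transform", {
  us <- make_umbrella_dataset(n_samples = 300, seed = 3)
  prof <- wham(us[[1]])
  expect_equal(attr(prof, "prob_total"), 1, tolerance = 1e-8)
  expect_true(all(diff(prof$xi) > 0))
  expect_equal(min(prof$free_energy), 0)
})

test_that("WHAM recovers a planted harmonic PMF under the 41-window
           layout", {
  us <- make_umbrella_dataset(n_samples = 1000, seed = 1)
  prof <- wham(us[[1]])
  truth <- attr(us, "truth")
  ctr <- prof$xi >= 15 & prof$xi <= 30
  expect_gt(sum(ctr), 100)
  expect_lt(profile_rmsd(prof$free_energy[ctr], truth(prof$xi[ctr])),
            0.3)
})

test_that("WHAM output is invariant to window order and symmetric for
           symmetric input", {
  us <- make_umbrella_dataset(n_samples = 400, seed = 9)
  p1 <- wham(us[[1]])
  p2 <- wham(rev(us[[1]]))
  expect_equal(p1$free_energy, p2$free_energy, tolerance = 1e-8)

  # two symmetric windows around a symmetric PMF
  set.seed(4)
  kT <- 0.0019872041 * 300
  target <- function(xi, ref) 0.5 * (xi - 20)^2 +
    bias_potential(xi, ref, 5)
  sample_win <- function(ref) {
    xs <- numeric(4000); x <- ref; e <- target(x, ref)
    for (i in seq_along(xs)) {
      xp <- x + runif(1, -0.4, 0.4)
      ep <- target(xp, ref)
      if (ep <= e || runif(1) < exp(-(ep - e) / kT)) { x <- xp; e <- ep }
      xs[i] <- x
    }
    xs
  }
  wins <- list(umbrella_window(19.5, 5, sample_win(19.5)),
               umbrella_window(20.5, 5, sample_win(20.5)))
  prof <- wham(wins, bin_width = 0.1)
  mid <- 20
  left <- prof$free_energy[order(abs(prof$xi - (mid - 0.35)))[1]]
  right <- prof$free_energy[order(abs(prof$xi - (mid + 0.35)))[1]]
  expect_lt(abs(left - right), 0.15)
})

test_that("round averaging uses the trailing rounds and beats the early
           ones under drift", {
  us <- make_umbrella_dataset(n_samples = 400, n_rounds = 18,
                              drift_amp = 3, seed = 11)
  profs <- lapply(us, wham)
  common <- Reduce(intersect, lapply(profs, function(p) p$xi))
  profs <- lapply(profs, function(p) {
    q <- p[p$xi %in% common, ]
    class(q) <- class(p)
    q
  })
  truth <- attr(us, "truth")
  avg_last <- average_pmf(profs, last_n = 10)
  avg_first <- average_pmf(profs[1:10], last_n = 10)
  ctr <- avg_last$xi >= 15 & avg_last$xi <= 30
  e_last <- profile_rmsd(avg_last$free_energy[ctr],
                         truth(avg_last$xi[ctr]))
  e_first <- profile_rmsd(avg_first$free_energy[ctr],
                          truth(avg_first$xi[ctr]))
  expect_lt(e_last, e_first)

  # identical rounds average to any round; alternating noise cancels
  p0 <- profs[[18]]
  same <- average_pmf(rep(list(p0), 10), last_n = 10)
  expect_equal(same$free_energy,
               p0$free_energy - min(p0$free_energy), tolerance = 1e-12)
  eps_prof <- lapply(1:10, function(k) {
    q <- p0
    q$free_energy <- q$free_energy + (-1)^k * 0.05
    q
  })
  cancel <- average_pmf(eps_prof, last_n = 10)
  expect_equal(cancel$free_energy,
               p0$free_energy - min(p0$free_energy), tolerance = 1e-10)

  expect_error(average_pmf(profs[1:5], last_n = 10), "at least 10")
})

test_that("pmf_delta measures well depth and ignores vertical shifts", {
  xi <- seq(10, 30, by = 0.1)
  kT <- 0.0019872041 * 300
  flat <- tibble::tibble(xi = xi, free_energy = rep(1.3, length(xi)),
                         count = 1)
  class(flat) <- c("pmf_profile", class(flat))
  expect_equal(pmf_delta(flat, c(12, 14), c(28, 30)), 0)

  depth <- 5 * kT
  well <- tibble::tibble(
    xi = xi,
    free_energy = pmin(depth, 0.5 * (xi - 12)^2),
    count = 1)
  class(well) <- c("pmf_profile", class(well))
  expect_equal(pmf_delta(well, c(11, 13), c(28, 30)), depth,
               tolerance = 1e-9)

  shifted <- well
  shifted$free_energy <- shifted$free_energy + 7
  expect_equal(pmf_delta(well, c(11, 13), c(28, 30)) -
                 pmf_delta(shifted, c(11, 13), c(28, 30)), 0)
  expect_error(pmf_delta(well, c(0, 1), c(28, 30)), "no PMF bins")
})

test_that("umbrella datasets round-trip through the on-disk layout", {
  us <- make_umbrella_dataset(n_samples = 50, n_rounds = 2, seed = 6)
  dir <- withr::local_tempdir()
  write_umbrella_dataset(us, dir)
  back <- read_umbrella_dataset(dir)
  expect_length(back, 2)
  expect_equal(back[[1]][[5]]$xi_ref, us[[1]][[5]]$xi_ref)
  expect_equal(back[[2]][[41]]$samples, us[[2]][[41]]$samples,
               tolerance = 1e-6)
})
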