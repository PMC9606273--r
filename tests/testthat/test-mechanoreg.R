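test_that("a quiescent solid cube yields exactly its surface as quiescent events", {
  n <- c(12, 12, 12)
  k <- 6L
  bone <- array(FALSE, n)
  bone[4:9, 4:9, 4:9] <- TRUE       # k^3 cube strictly inside the grid
  labels <- array(0L, n)
  labels[bone] <- 3L
  lab <- remodelr:::new_remodeling_labels(labels, 320, array(TRUE, n))
  strain <- array(5000, n)
  ev <- extract_surface_events(lab, bone, strain)
  expect_equal(nrow(ev), 6 * k^2 - 12 * k + 8)
  expect_true(all(ev$type == "quiescent"))
  expect_true(all(ev$eps_eff == 5000))
})

test_that("a single resorbed voxel on a flat face is one resorption event with its own strain", {
  n <- c(12, 12, 12)
  bone <- array(FALSE, n)
  bone[4:9, 4:9, 4:9] <- TRUE
  labels <- array(0L, n)
  labels[bone] <- 3L
  labels[6, 6, 9] <- 2L             # resorbed on the top face
  lab <- remodelr:::new_remodeling_labels(labels, 320, array(TRUE, n))
  strain <- array(5000, n)
  strain[6, 6, 9] <- 1234
  ev <- extract_surface_events(lab, bone, strain)
  res <- ev[ev$type == "resorbed", ]
  expect_identical(nrow(res), 1L)
  expect_identical(res$eps_eff, 1234)
})

test_that("formed voxels inherit the adjacent baseline element's strain", {
  n <- c(8, 8, 8)
  bone <- array(FALSE, n)
  bone[3:6, 3:6, 3:5] <- TRUE
  labels <- array(0L, n)
  labels[bone] <- 3L
  labels[4, 4, 6] <- 1L             # formed atop the surface
  lab <- remodelr:::new_remodeling_labels(labels, 320, array(TRUE, n))
  strain <- array(NA_real_, n)
  strain[bone] <- 3000
  strain[4, 4, 5] <- 7777           # the face-adjacent donor below
  ev <- extract_surface_events(lab, bone, strain)
  expect_identical(ev$eps_eff[ev$type == "formed"], 7777)
})

test_that("covered quiescent surface voxels are suppressed unless requested", {
  n <- c(8, 8, 8)
  bone <- array(FALSE, n)
  bone[3:6, 3:6, 3:5] <- TRUE
  labels <- array(0L, n)
  labels[bone] <- 3L
  labels[4, 4, 6] <- 1L
  lab <- remodelr:::new_remodeling_labels(labels, 320, array(TRUE, n))
  strain <- array(1000, n)
  ev <- extract_surface_events(lab, bone, strain)
  ev_all <- extract_surface_events(lab, bone, strain,
                                   include_covered_quiescent = TRUE)
  expect_identical(nrow(ev_all) - nrow(ev), 1L)   # the covered parent voxel
})

test_that("strain normalization is scale-invariant and validates its constant", {
  ev <- tibble::tibble(voxel = 1:4,
                       type = factor(rep("quiescent", 4),
                                     levels = c("formed", "quiescent",
                                                "resorbed")),
                       eps_eff = c(100, 200, 300, 27900),
                       strain_norm = NA_real_)
  nv <- normalize_strains(ev, 27900)
  expect_equal(nv$strain_norm[4], 1)
  ev_half <- ev
  ev_half$eps_eff <- ev$eps_eff / 2
  half <- normalize_strains(ev_half, 27900 / 2)
  expect_equal(half$strain_norm, nv$strain_norm, tolerance = 1e-12)
  expect_error(normalize_strains(ev, 0), "positive")
  expect_error(normalize_strains(ev, -5), "positive")
})

test_that("CP bins condition correctly and sum to one under both weightings", {
  ev <- tibble::tibble(
    voxel = 1:10,
    type = factor(c(rep("formed", 2), rep("quiescent", 5),
                    rep("resorbed", 3)),
                  levels = c("formed", "quiescent", "resorbed")),
    eps_eff = rep(5000, 10),
    strain_norm = rep(0.155, 10))
  cp <- cp_curves(ev, min_count = 1)
  b <- cp$bins[cp$bins$n_F + cp$bins$n_Q + cp$bins$n_R > 0, ]
  expect_identical(nrow(b), 1L)
  expect_equal(c(b$p_F, b$p_Q, b$p_R), c(0.2, 0.5, 0.3))

  # equal type priors: weights 1/N_t, renormalized per bin
  cpe <- cp_curves(ev, min_count = 1, type_weights = "equal")
  be <- cpe$bins[cpe$bins$n_F > 0, ]
  expect_equal(c(be$p_F, be$p_Q, be$p_R), c(1, 1, 1) / 3, tolerance = 1e-12)

  # all-formation events give p_F = 1 in every occupied bin
  evf <- ev
  evf$type <- factor("formed", levels = levels(ev$type))
  cpf <- cp_curves(evf, min_count = 1)
  occ <- cpf$bins$n_F > 0
  expect_true(all(cpf$bins$p_F[occ] == 1))
})

test_that("strain-independent event types give CP within binomial bounds per bin", {
  set.seed(11)
  n <- 20000
  probs <- c(formed = 0.3, quiescent = 0.5, resorbed = 0.2)
  ev <- tibble::tibble(
    voxel = seq_len(n),
    type = factor(sample(names(probs), n, replace = TRUE, prob = probs),
                  levels = c("formed", "quiescent", "resorbed")),
    eps_eff = runif(n, 0, 28000),
    strain_norm = NA_real_)
  ev <- normalize_strains(ev, 27900)
  cp <- cp_curves(ev, min_count = 10)
  b <- cp$bins[cp$bins$occupied, ]
  tot <- b$n_F + b$n_Q + b$n_R
  z <- qnorm(0.995)
  for (tp in names(probs)) {
    p <- b[[c(formed = "p_F", quiescent = "p_Q", resorbed = "p_R")[[tp]]]]
    bound <- z * sqrt(probs[[tp]] * (1 - probs[[tp]]) / tot)
    # 99% CI per bin: allow a small number of excursions across ~100 bins
    expect_lt(mean(abs(p - probs[[tp]]) > bound), 0.05)
  }
})

test_that("thresholds are read off a constructed step-function CP exactly", {
  mk <- function(centers, nF, nQ, nR) {
    do.call(rbind, lapply(seq_along(centers), function(i) {
      tibble::tibble(
        voxel = 1L,
        type = factor(c(rep("formed", nF[i]), rep("quiescent", nQ[i]),
                        rep("resorbed", nR[i])),
                      levels = c("formed", "quiescent", "resorbed")),
        eps_eff = 1, strain_norm = centers[i])
    }))
  }
  centers <- seq(0.005, 0.495, by = 0.01)
  nF <- ifelse(centers > 0.23, 60L, 10L)
  nR <- ifelse(centers < 0.08, 60L, 10L)
  nQ <- ifelse(centers >= 0.08 & centers <= 0.23, 60L, 15L)
  ev <- mk(centers, nF, nQ, nR)
  th <- derive_thresholds(cp_curves(ev, min_count = 10))
  expect_equal(unname(th), c(0.08, 0.23))

  allq <- mk(centers, rep(0L, length(centers)), rep(30L, length(centers)),
             rep(0L, length(centers)))
  expect_identical(unname(derive_thresholds(cp_curves(allq))),
                   c(NA_real_, NA_real_))
})

test_that("the persistence rule ignores an isolated dominance blip", {
  centers <- seq(0.005, 0.395, by = 0.01)
  nF <- ifelse(centers > 0.30, 60L, 5L)
  nF[centers > 0.12 & centers < 0.13] <- 80L    # single-bin blip
  nQ <- rep(30L, length(centers))
  nR <- ifelse(centers < 0.05, 80L, 5L)
  ev <- do.call(rbind, lapply(seq_along(centers), function(i) {
    tibble::tibble(voxel = 1L,
                   type = factor(c(rep("formed", nF[i]),
                                   rep("quiescent", nQ[i]),
                                   rep("resorbed", nR[i])),
                                 levels = c("formed", "quiescent",
                                            "resorbed")),
                   eps_eff = 1, strain_norm = centers[i])
  }))
  th <- derive_thresholds(cp_curves(ev, min_count = 10))
  expect_equal(th[["Tf"]], 0.30)   # not the 0.12 blip
  expect_equal(th[["Tr"]], 0.05)
})

test_that("CCR is exact for obeyed step rules and near chance for shuffled types", {
  set.seed(12)
  n <- 100000
  s <- runif(n, 0, 1)
  type <- ifelse(s < 0.08, "resorbed", ifelse(s > 0.23, "formed",
                                              "quiescent"))
  ev <- tibble::tibble(voxel = seq_len(n),
                       type = factor(type, levels = c("formed", "quiescent",
                                                      "resorbed")),
                       eps_eff = s, strain_norm = s)
  expect_equal(ccr(ev, c(Tr = 0.08, Tf = 0.23)), 1)

  # uniformly random types: CCR = 1/3 within 0.01
  ev$type <- factor(sample(c("formed", "quiescent", "resorbed"), n,
                           replace = TRUE),
                    levels = levels(ev$type))
  expect_lt(abs(ccr(ev, c(Tr = 0.08, Tf = 0.23)) - 1 / 3), 0.01)

  expect_error(ccr(ev, c(Tr = NA_real_, Tf = 0.23)), "undefined")
})

test_that("CP plots build without error", {
  set.seed(13)
  ev <- tibble::tibble(voxel = 1:300,
                       type = factor(sample(c("formed", "quiescent",
                                              "resorbed"), 300, TRUE),
                                     levels = c("formed", "quiescent",
                                                "resorbed")),
                       eps_eff = runif(300, 0, 28000),
                       strain_norm = NA_real_)
  ev <- normalize_strains(ev, 27900)
  cp <- cp_curves(ev)
  expect_s3_class(ggplot2::autoplot(cp, thresholds = c(0.1, 0.3)), "ggplot")
})
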