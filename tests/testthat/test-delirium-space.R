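test_that("diagnosis recovers a planted POD subgroup", {
  ctrl <- group_profile("control-like")
  podp <- group_profile("POD-like")
  control <- animal_fractions(ctrl, 20, seed = 1)
  mix <- rbind(animal_fractions(podp, 10, seed = 2),
               animal_fractions(ctrl, 10, seed = 3))
  d <- diagnose_pod(mix, control)
  truth <- rep(c("POD", "nonPOD"), each = 10)
  expect_gte(ari(d$labels, truth), 0.9)
  expect_lt(d$gate_p, 0.05)
})

test_that("model animals indistinguishable from controls stay nonPOD", {
  ctrl <- group_profile("control-like")
  control <- animal_fractions(ctrl, 20, seed = 4)
  null_model <- animal_fractions(ctrl, 20, seed = 5)
  d <- diagnose_pod(null_model, control)
  expect_gte(mean(d$labels == "nonPOD"), 0.9)

  # a single model sample copied from a control animal
  single <- diagnose_pod(control[7, , drop = FALSE], control)
  expect_equal(single$labels, "nonPOD")

  X <- matrix(0.025, 10, 40)
  expect_error(diagnose_pod(X[1:5, ], X[6:10, ]), "degenerate")
})

test_that("embedding is deterministic, equivariant and separability-preserving", {
  set.seed(9)
  X <- rbind(matrix(stats::rnorm(10 * 14, 0), 10),
             matrix(stats::rnorm(10 * 14, 10), 10))
  Y <- embed_fractions(X, seed = 1)
  expect_equal(dim(Y), c(20L, 3L))
  expect_identical(Y, embed_fractions(X, seed = 1))

  perm <- sample(20)
  Y2 <- embed_fractions(X[perm, ], seed = 1)
  expect_equal(Y2[order(perm), ], Y, tolerance = 1e-8, ignore_attr = TRUE)

  # 10-SD-separated blobs stay linearly separable after embedding
  lab <- rep(c("a", "b"), each = 10)
  bd <- fit_boundary(Y, lab)
  scores <- drop(as.matrix(Y) %*% bd$w + bd$b)
  expect_true(all((scores > 0) == (lab == bd$positive)))

  expect_error(embed_fractions(X[1:3, ]), "4 samples")
  expect_error(embed_fractions(X[1:5, ], neighbor_param = 6), "too large")
})

test_that("the max-margin boundary matches the symmetric toy solution", {
  Y <- rbind(c(-1, 0, 0), c(1, 0, 0))
  bd <- fit_boundary(Y, c("neg", "pos"))
  wn <- bd$w / sqrt(sum(bd$w^2))
  expect_equal(abs(unname(wn[1])), 1, tolerance = 1e-6)
  expect_equal(bd$b, 0, tolerance = 1e-6)
  expect_error(fit_boundary(Y, c("a", "a")), "two label")

  # non-separable data: reported decision values are self-consistent
  set.seed(3)
  Yo <- matrix(stats::rnorm(60), 20, 3)
  lab <- rep(c("a", "b"), 10)
  bdo <- fit_boundary(Yo, lab)
  pred_svm <- as.character(predict(bdo$svm, Yo))
  scores <- drop(Yo %*% bdo$w + bdo$b)
  pred_manual <- ifelse(scores > 0, bdo$positive,
                        setdiff(c("a", "b"), bdo$positive))
  expect_equal(pred_manual, pred_svm)
})

test_that("projection is a signed scaled distance with stable conventions", {
  bd <- list(w = c(1, 0, 0), b = 0, positive = "POD")
  expect_equal(project_onto_boundary(rbind(c(2, 0, 0)), bd, "POD"), 2)
  expect_equal(project_onto_boundary(rbind(c(0, 5, -3)), bd, "POD"), 0)
  pts <- rbind(c(1.5, 2, 1), c(-1.5, 2, 1))
  pr <- project_onto_boundary(pts, bd, "POD")
  expect_equal(pr[1], -pr[2])

  # invariance to positive rescaling of (w, b)
  bd2 <- list(w = 10 * bd$w, b = 10 * bd$b, positive = "POD")
  expect_equal(project_onto_boundary(pts, bd2, "POD"),
               project_onto_boundary(pts, bd, "POD"))
  # raw decision values scale with w
  expect_equal(project_onto_boundary(pts, bd2, "POD", raw = TRUE),
               10 * project_onto_boundary(pts, bd, "POD", raw = TRUE))
  expect_error(project_onto_boundary(pts, list(w = c(0, 0, 0), b = 1,
                                               positive = "POD")),
               "degenerate")
})

test_that("the fitted behaviour space separates diagnosed groups end-to-end", {
  ctrl <- group_profile("control-like")
  podp <- group_profile("POD-like")
  control <- animal_fractions(ctrl, 20, seed = 11)
  mix <- rbind(animal_fractions(podp, 10, seed = 12),
               animal_fractions(ctrl, 10, seed = 13))
  sp <- pod_space(mix, control, seed = 14)
  expect_s3_class(sp, "pod_space")
  expect_setequal(sp$movements, sort(unlist(discriminative_movements())))
  expect_gt(min(sp$projection[sp$labels == "POD"]),
            max(sp$projection[sp$labels == "nonPOD"]))
  sm <- summary(sp)
  expect_true(all(c("projection_mean", "n") %in% names(sm)))

  # treated animals resembling controls project to the nonPOD side
  treated <- animal_fractions(ctrl, 10, seed = 15)
  pred <- predict(sp, treated)
  expect_gte(mean(pred$label == "nonPOD"), 0.9)
})
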