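#' Default pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param n_control,n_model,n_dex animals per group.
#' @param n_frames frames per simulated session (default 10 min at 30 fps).
#' @param effect_size POD-profile shift, in between-animal SDs.
#' @param pod_fraction_model,pod_fraction_dex share of each group generated
#'   from the POD-like profile.
#' @param out_dir directory for CSV/JSON outputs (NULL: in-memory only).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_control = 20, n_model = 20,
                            n_dex = 20, n_frames = 18000, effect_size = 3,
                            pod_fraction_model = 0.6, pod_fraction_dex = 0.3,
                            out_dir = NULL) {
  structure(list(seed = seed, n_control = n_control, n_model = n_model,
                 n_dex = n_dex, n_frames = n_frames,
                 effect_size = effect_size,
                 pod_fraction_model = pod_fraction_model,
                 pod_fraction_dex = pod_fraction_dex, out_dir = out_dir),
            class = "pipeline_config")
}

# mixture group: some animals from the POD-like profile, the rest
# control-like; returns fractions matrix plus ground-truth labels
.mixture_group <- function(n, pod_fraction, effect_size, seed) {
  n_pod <- round(n * pod_fraction)
  ctrl <- group_profile("control-like", effect_size = effect_size)
  podp <- group_profile("POD-like", effect_size = effect_size)
  X <- rbind(
    if (n_pod > 0) animal_fractions(podp, n_pod, seed) else NULL,
    if (n - n_pod > 0) animal_fractions(ctrl, n - n_pod, seed + 1) else NULL)
  list(X = X, truth = rep(c("POD", "nonPOD"), c(n_pod, n - n_pod)))
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Simulates control, model and treated groups under the configured study
#' conditions, then runs every analysis stage: movement-fraction statistics
#' and discriminative-movement selection, POD diagnosis and the embedded
#' behaviour space with projection values, Hyper/Hypo subtype clustering on
#' pose summaries, treatment classification with incidence, and an
#' investigation-session recovery demonstration. All randomness derives
#' from `config$seed`; when `config$out_dir` is set, each stage also writes
#' its table there.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pod_pipeline` bundling all stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  s <- config$seed
  message("simulate: fraction vectors (control n=", config$n_control,
          ", model n=", config$n_model, ", dex n=", config$n_dex, ")")
  ctrl <- group_profile("control-like", effect_size = config$effect_size)
  control <- animal_fractions(ctrl, config$n_control, seed = s)
  model <- .mixture_group(config$n_model, config$pod_fraction_model,
                          config$effect_size, seed = s + 10)
  dexg <- .mixture_group(config$n_dex, config$pod_fraction_dex,
                         config$effect_size, seed = s + 20)

  message("diagnose: behaviour-space fit")
  space <- pod_space(model$X, control, seed = s)

  message("metrics: discriminative movements POD vs nonPOD")
  comparison <- space$comparison

  message("dex-eval: classifier and incidence")
  clf <- train_classifier(model$X[, space$movements, drop = FALSE],
                          space$diagnosis$labels, seed = s)
  incidence <- predict_and_incidence(clf,
                                     dexg$X[, space$movements, drop = FALSE])
  model_incidence <- predict_and_incidence(clf,
                                           model$X[, space$movements,
                                                   drop = FALSE])

  message("subtype: Hyper/Hypo clustering on pose summaries")
  # subtype demonstration cohort: at least 5 animals per subtype so the
  # 3-D embedding's neighbourhood parameter stays valid
  n_pod <- sum(space$diagnosis$labels == "POD")
  n_hyper <- max(5, round(n_pod / 2))
  n_hypo <- max(5, n_pod - n_hyper)
  arena <- open_field_arena()
  sub_frames <- min(config$n_frames, 2500L)
  trajs <- c(
    lapply(seq_len(n_hyper), function(i)
      generate_skeleton(kinematic_profile("Hyper"), arena, sub_frames,
                        seed = s + 100 + i)),
    lapply(seq_len(n_hypo), function(i)
      generate_skeleton(kinematic_profile("Hypo"), arena, sub_frames,
                        seed = s + 200 + i)))
  E <- do.call(rbind, lapply(trajs, eigenvalue_vector, on = "values"))
  subtypes <- cluster_subtypes(E, seed = s)
  subtype_truth <- rep(c("Hyper", "Hypo"), c(n_hyper, n_hypo))

  message("investigate: scheduled-session recovery")
  sched <- investigation_schedule(
    start = c(301, 901, 1501, 2101, 2701, 3301),
    end = c(420, 1020, 1620, 2220, 2820, 3420),
    role = rep(c("familiar", "novel"), 3),
    depth = rep(c("deep", "shallow"), each = 3),
    n_frames = 3900)
  nor <- nor_arena()
  itraj <- generate_investigation_session(sched, nor,
                                          kinematic_profile("Hyper"),
                                          seed = s + 300)
  invest <- investigation_record(itraj, nor)

  out <- structure(list(config = config, control = control,
                        model = model$X, model_truth = model$truth,
                        dex = dexg$X, dex_truth = dexg$truth,
                        space = space, comparison = comparison,
                        classifier = clf, incidence = incidence,
                        model_incidence = model_incidence,
                        subtypes = subtypes, subtype_truth = subtype_truth,
                        eigen_matrix = E, investigation = invest),
                   class = "pod_pipeline")
  if (!is.null(config$out_dir)) .write_pipeline(out, config$out_dir)
  out
}

.write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(data.frame(animal = seq_along(x$space$labels),
               label = x$space$labels,
               projection = x$space$projection), "diagnosis.csv")
  if (!is.null(x$comparison)) w(as.data.frame(x$comparison), "movements.csv")
  w(data.frame(animal = seq_along(x$subtypes$subtype),
               subtype = x$subtypes$subtype,
               cluster = x$subtypes$cluster), "subtypes.csv")
  w(x$investigation$bouts, "investigation_bouts.csv")
  w(data.frame(candidate = seq_along(x$classifier$cv_error),
               lambda = x$classifier$lambdas,
               cv_error = x$classifier$cv_error,
               best_so_far = x$classifier$error_curve), "cv_curve.csv")
  jsonlite::write_json(
    list(seed = x$config$seed,
         incidence_dex = x$incidence$incidence,
         incidence_model = x$model_incidence$incidence,
         dsp = x$investigation$dsp),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @export
print.pod_pipeline <- function(x, ...) {
  cat("Synthetic POD pipeline (seed ", x$config$seed, ")\n", sep = "")
  print(x$space)
  print(x$incidence)
  print(x$subtypes)
  print(x$investigation)
  invisible(x)
}
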