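# Benchmark orchestration: model families x training plans on a dataset,
# per-neuron metric tables and directional-ordering reports.

legal_run <- function(family, plan) {
  switch(plan,
    simul = TRUE,
    incr = family == "rf_sa_star",
    incr_fc1 = ,
    incr_fc2 = family == "ff_sa_star",
    FALSE)
}

#' Benchmark configuration
#'
#' @param runs Data frame with columns `family` and `plan` (plan one of
#'   `"simul"`, `"incr"`, `"incr_fc1"`, `"incr_fc2"`); every pair must be a
#'   legal combination.
#' @param channels_c Trunk channels for all models.
#' @param train A [train_config()]; its seed is the base seed.
#' @param n_seeds Independent fits per (run, neuron).
#' @param top_fraction Peak-tuning fraction.
#' @param neurons Optional neuron indices (default: all in the dataset).
#' @return A `sacnn_benchmark_config`.
#' @export
benchmark_config <- function(runs, channels_c = 8L, train = train_config(),
                             n_seeds = 1L, top_fraction = 0.01,
                             neurons = NULL) {
  stopifnot(is.data.frame(runs), all(c("family", "plan") %in% names(runs)))
  ok <- mapply(legal_run, runs$family, runs$plan)
  if (!all(ok))
    stop("illegal (family, plan) pair(s): ",
         paste(runs$family[!ok], runs$plan[!ok], sep = ":", collapse = ", "))
  structure(list(runs = runs, channels_c = as.integer(channels_c),
                 train = train, n_seeds = as.integer(n_seeds),
                 top_fraction = top_fraction, neurons = neurons),
            class = "sacnn_benchmark_config")
}

#' Run a model-comparison benchmark
#'
#' For every (family, plan) x seed x neuron, trains the plan on the training
#' split and evaluates the final-stage model on the validation split:
#' Pearson correlation against the repeat-mean response, PTJ, PTS, and (when
#' repeats are available) CCnorm. Failed fits are recorded with their reason
#' and excluded from summaries, never silently dropped.
#'
#' @param dataset A [synth_dataset()] (or compatible `sacnn_dataset`).
#' @param config A [benchmark_config()].
#' @return A `sacnn_benchmark`: list with `per_neuron` (data frame),
#'   `failures` (data frame), `config`.
#' @export
run_benchmark <- function(dataset, config) {
  stopifnot(inherits(dataset, "sacnn_dataset"),
            inherits(config, "sacnn_benchmark_config"))
  tr_x <- dataset$train$stimuli
  va_x <- dataset$val$stimuli
  neurons <- config$neurons
  if (is.null(neurons)) neurons <- seq_along(dataset$bank$neurons)
  rows <- list(); fails <- list()
  side <- tr_x$side
  for (ri in seq_len(nrow(config$runs))) {
    family <- config$runs$family[ri]
    plan_name <- config$runs$plan[ri]
    for (sd_i in seq_len(config$n_seeds)) {
      for (ni in neurons) {
        y_tr <- dataset$train$responses$responses[ni, ]
        cfg <- config$train
        cfg$seed <- cfg$seed + 1000L * (sd_i - 1L) + 17L * ni + ri
        plan <- if (plan_name == "simul")
          stage_plan_preset("simul", config$channels_c, side, family = family)
        else stage_plan_preset(plan_name, config$channels_c, side)
        res <- tryCatch({
          stages <- run_plan(plan, tr_x, y_tr, cfg)
          final <- stages[[length(stages)]]$model
          ev <- evaluate_model(final, va_x, dataset$val$responses, ni,
                               config$top_fraction)
          cbind(data.frame(neuron = ni, family = family, plan = plan_name,
                           seed = cfg$seed, stringsAsFactors = FALSE), ev)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          fails[[length(fails) + 1]] <-
            data.frame(neuron = ni, family = family, plan = plan_name,
                       seed = cfg$seed, reason = conditionMessage(res),
                       stringsAsFactors = FALSE)
        } else rows[[length(rows) + 1]] <- res
      }
    }
  }
  structure(list(
    per_neuron = if (length(rows)) do.call(rbind, rows) else NULL,
    failures = if (length(fails)) do.call(rbind, fails) else NULL,
    config = config), class = "sacnn_benchmark")
}

#' Evaluate one trained model on a validation split
#'
#' @param model A trained `sacnn_model`.
#' @param stimuli Validation stimuli.
#' @param responses A `sacnn_responses` for the validation set.
#' @param neuron Neuron index within `responses`.
#' @param top_fraction Peak-tuning fraction.
#' @return One-row data frame: `corr`, `ptj`, `pts`, `ccnorm`, `n_images`.
#' @export
evaluate_model <- function(model, stimuli, responses, neuron,
                           top_fraction = 0.01) {
  pred <- predict(model, stimuli)
  real <- responses$responses[neuron, ]
  ccn <- NA_real_
  if (!is.null(responses$repeats)) {
    ccn <- tryCatch(
      normalized_correlation(pred, responses$repeats[neuron, , ])$ccnorm,
      error = function(e) NA_real_)
  }
  data.frame(
    corr = pearson_cor(pred, real),
    ptj = peak_tuning(pred, real, top_fraction, "joint")$pt_percent,
    pts = peak_tuning(pred, real, top_fraction, "separate")$pt_percent,
    ccnorm = ccn, n_images = length(pred))
}

#' Summarize a benchmark as a model-comparison table
#'
#' Metrics are averaged over seeds within neuron first, then mean and SEM
#' are taken across neurons per (family, plan). The correlation column also
#' carries a percentage difference versus a baseline model row.
#'
#' @param benchmark A [run_benchmark()] result (or its `per_neuron` frame).
#' @param baseline `c(family, plan)` of the reference row; default the first
#'   (family, plan) in the table.
#' @return Data frame with one row per (family, plan): mean and SEM of every
#'   metric plus `delta_corr_pct`.
#' @export
summarize_benchmark <- function(benchmark, baseline = NULL) {
  pn <- if (inherits(benchmark, "sacnn_benchmark")) benchmark$per_neuron
        else benchmark
  stopifnot(is.data.frame(pn), nrow(pn) > 0)
  # average over seeds within neuron
  agg <- aggregate(pn[c("corr", "ptj", "pts", "ccnorm")],
                   by = list(family = pn$family, plan = pn$plan,
                             neuron = pn$neuron), FUN = mean)
  sem <- function(v) sd(v) / sqrt(length(v))
  mod_key <- paste(agg$family, agg$plan, sep = ":")
  out <- do.call(rbind, lapply(unique(mod_key), function(k) {
    a <- agg[mod_key == k, ]
    data.frame(family = a$family[1], plan = a$plan[1], n_neurons = nrow(a),
               corr = mean(a$corr), corr_sem = sem(a$corr),
               ptj = mean(a$ptj), ptj_sem = sem(a$ptj),
               pts = mean(a$pts), pts_sem = sem(a$pts),
               ccnorm = mean(a$ccnorm), ccnorm_sem = sem(a$ccnorm),
               stringsAsFactors = FALSE)
  }))
  if (is.null(baseline)) baseline <- c(out$family[1], out$plan[1])
  base_row <- out[out$family == baseline[1] & out$plan == baseline[2], ]
  if (nrow(base_row) != 1) stop("baseline model not in benchmark")
  out$delta_corr_pct <- 100 * (out$corr - base_row$corr) / base_row$corr
  rownames(out) <- NULL
  out
}

#' Evaluate directional expectations on a benchmark
#'
#' Each expectation declares that `model_a` should be at least as good as
#' `model_b` on a metric. The comparison is paired across neurons (seed
#' averages), reporting the mean difference, the number of neurons favoring
#' each side, and a one-sided sign-test p-value. Comparing a model with
#' itself reports direction `"none"`.
#'
#' @param benchmark A [run_benchmark()] result (or its `per_neuron` frame).
#' @param expectations Data frame with columns `metric`, `family_a`,
#'   `plan_a`, `family_b`, `plan_b`.
#' @return Data frame: one row per expectation with `mean_diff`, `n_pos`,
#'   `n_neg`, `p_sign`, `direction`.
#' @export
compare_orderings <- function(benchmark, expectations) {
  pn <- if (inherits(benchmark, "sacnn_benchmark")) benchmark$per_neuron
        else benchmark
  agg <- aggregate(pn[c("corr", "ptj", "pts", "ccnorm")],
                   by = list(family = pn$family, plan = pn$plan,
                             neuron = pn$neuron), FUN = mean)
  one <- function(metric, fa, pa, fb, pb) {
    a <- agg[agg$family == fa & agg$plan == pa, ]
    b <- agg[agg$family == fb & agg$plan == pb, ]
    if (nrow(a) == 0 || nrow(b) == 0)
      stop("expectation references a model absent from the benchmark: ",
           fa, ":", pa, " vs ", fb, ":", pb)
    m <- merge(a, b, by = "neuron", suffixes = c("_a", "_b"))
    da <- m[[paste0(metric, "_a")]] - m[[paste0(metric, "_b")]]
    n_pos <- sum(da > 0); n_neg <- sum(da < 0)
    p <- if (n_pos + n_neg == 0) NA_real_ else
      binom.test(n_pos, n_pos + n_neg, alternative = "greater")$p.value
    data.frame(metric = metric, model_a = paste(fa, pa, sep = ":"),
               model_b = paste(fb, pb, sep = ":"),
               mean_diff = mean(da), n_pos = n_pos, n_neg = n_neg,
               p_sign = p,
               direction = if (n_pos + n_neg == 0) "none" else
                 if (mean(da) > 0) "a_better" else
                   if (mean(da) < 0) "b_better" else "none",
               stringsAsFactors = FALSE)
  }
  do.call(rbind, Map(one, expectations$metric, expectations$family_a,
                     expectations$plan_a, expectations$family_b,
                     expectations$plan_b))
}
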