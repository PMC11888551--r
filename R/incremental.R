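#' Copy block weights between shape-compatible models
#'
#' After inheritance the target's forward activations through each inherited
#' block match the source's exactly.
#'
#' @param source_model,target_model `sacnn_model`s.
#' @param blocks Character vector of block ids to copy.
#' @return The target model with inherited weights.
#' @export
inherit_weights <- function(source_model, target_model, blocks) {
  for (id in blocks) {
    if (!id %in% block_ids(source_model) || !id %in% block_ids(target_model))
      stop("block '", id, "' not present in both models")
    src <- source_model$blocks[[id]]$params
    tgt <- target_model$blocks[[id]]$params
    for (pn in names(tgt)) {
      ds <- dim(src[[pn]]); dt <- dim(tgt[[pn]])
      if (!identical(ds, dt) || length(src[[pn]]) != length(tgt[[pn]]))
        stop("shape mismatch in block '", id, "' parameter '", pn, "'")
      target_model$blocks[[id]]$params[[pn]] <- src[[pn]]
    }
  }
  target_model
}

#' Expand a center-hypercolumn readout into a fully connected readout
#'
#' Converts a CTL model into its FCL counterpart (e.g. the attention model
#' with center readout into the same trunk with a dense readout over all
#' hypercolumns). The FCL weights on the center hypercolumn are initialized
#' from the CTL weights and all surround weights start at zero, so the
#' expanded model's predictions equal the parent's on every image at
#' initialization, exactly. Mode `"FC1"` marks the center column and the bias
#' frozen (only surround weights can be learned); `"FC2"` leaves the whole
#' readout trainable. All pre-readout blocks are inherited and, by
#' convention, frozen during the subsequent stage (see [run_plan()]).
#'
#' @param ctl_model A `sacnn_model` with a CTL readout.
#' @param mode `"FC1"` or `"FC2"`.
#' @return A list with `model` (the FCL model) and `frozen_blocks` (all
#'   pre-readout block ids).
#' @export
expand_readout <- function(ctl_model, mode = c("FC1", "FC2")) {
  mode <- match.arg(mode)
  spec <- ctl_model$spec
  if (spec$readout != "CTL")
    stop("expand_readout expects a CTL model; got readout ", spec$readout)
  tab <- family_table()
  same_gamma <- ifelse(is.na(tab$sa_gamma) | is.na(spec$sa_gamma),
                       is.na(tab$sa_gamma) == is.na(spec$sa_gamma),
                       tab$sa_gamma == spec$sa_gamma)
  hit <- tab[tab$beta_kernel_k == spec$beta_kernel_k & tab$readout == "FCL" &
             tab$sa_present == spec$sa_present & same_gamma, ]
  if (nrow(hit) != 1)
    stop("no FCL family matches this trunk (family ", spec$family, ")")
  fspec <- model_spec(hit$family, spec$channels_c, spec$input_side)
  fmodel <- assemble_model(fspec, seed = ctl_model$seed)
  pre <- setdiff(block_ids(fmodel), "readout")
  fmodel <- inherit_weights(ctl_model, fmodel, pre)

  side <- readout_side(fspec)
  c <- fspec$channels_c
  ic <- side %/% 2 + 1; jc <- side %/% 2 + 1
  W <- array(0, c(side, side, c))
  W[ic, jc, ] <- ctl_model$blocks$readout$params$W
  fmodel$blocks$readout$params$W <- W
  fmodel$blocks$readout$params$b <- ctl_model$blocks$readout$params$b
  if (mode == "FC1") {
    mask <- array(0, c(side, side, c))
    mask[ic, jc, ] <- 1
    fmodel$blocks$readout$freeze_mask <- list(W = mask, b = 1)
  }
  list(model = fmodel, frozen_blocks = pre)
}

#' Stage directive and stage plan constructors
#'
#' A stage plan is an ordered list of directives; each directive names the
#' architecture trained at that stage, which blocks it inherits from an
#' earlier stage, which blocks stay frozen, and how the readout is
#' initialized (`"fresh"`, or `"center_from_ctl"` to expand the previous
#' stage's CTL readout via [expand_readout()]).
#'
#' @param stage_name Stage label.
#' @param spec A [model_spec()].
#' @param inherit_from `NULL`, or `list(stage = <earlier stage name>,
#'   blocks = <block ids>)`.
#' @param frozen_blocks Block ids frozen during this stage's training.
#' @param readout_init `"fresh"` or `"center_from_ctl"`.
#' @param fc_mode For `"center_from_ctl"`: `"FC1"` or `"FC2"`.
#' @return A `sacnn_stage` / `sacnn_plan`.
#' @export
stage_directive <- function(stage_name, spec, inherit_from = NULL,
                            frozen_blocks = character(),
                            readout_init = c("fresh", "center_from_ctl"),
                            fc_mode = "FC2") {
  readout_init <- match.arg(readout_init)
  structure(list(stage_name = stage_name, spec = spec,
                 inherit_from = inherit_from,
                 frozen_blocks = frozen_blocks,
                 readout_init = readout_init, fc_mode = fc_mode),
            class = "sacnn_stage")
}

#' @rdname stage_directive
#' @param ... `sacnn_stage` directives in order.
#' @export
stage_plan <- function(...) {
  stages <- list(...)
  stopifnot(all(vapply(stages, inherits, logical(1), "sacnn_stage")))
  names(stages) <- vapply(stages, `[[`, character(1), "stage_name")
  if (anyDuplicated(names(stages))) stop("duplicate stage names")
  for (i in seq_along(stages)) {
    inh <- stages[[i]]$inherit_from
    if (!is.null(inh)) {
      pos <- match(inh$stage, names(stages))
      if (is.na(pos) || pos >= i)
        stop("stage '", names(stages)[i], "' inherits from '", inh$stage,
             "', which is not an earlier stage")
    }
  }
  structure(stages, class = "sacnn_plan")
}

#' Canonical training plans
#'
#' Named presets: `"simul"` trains the given family in a single stage;
#' `"incr"` trains the receptive-field model first and then the attention
#' model with a center readout (alpha blocks inherited and frozen);
#' `"incr_fc1"` / `"incr_fc2"` add a third stage that expands the center
#' readout into a fully connected readout (center column frozen for FC1,
#' free for FC2), with all pre-readout blocks inherited and frozen so the
#' final stage isolates the readout.
#'
#' @param preset One of `"simul"`, `"incr"`, `"incr_fc1"`, `"incr_fc2"`.
#' @param channels_c Trunk channel count.
#' @param input_side Input image side.
#' @param family For `"simul"` only: the family to train.
#' @return A `sacnn_plan`.
#' @export
stage_plan_preset <- function(preset = c("simul", "incr", "incr_fc1",
                                         "incr_fc2"),
                              channels_c, input_side = 50L,
                              family = "ff_sa_star") {
  preset <- match.arg(preset)
  rf <- model_spec("rf", channels_c, input_side)
  rfsa <- model_spec("rf_sa_star", channels_c, input_side)
  if (preset == "simul")
    return(stage_plan(stage_directive(
      "simul", model_spec(family, channels_c, input_side))))
  s1 <- stage_directive("rf", rf)
  s2 <- stage_directive("rf_sa_star",
                        rfsa,
                        inherit_from = list(stage = "rf",
                                            blocks = c("alpha1", "alpha2")),
                        frozen_blocks = c("alpha1", "alpha2"))
  if (preset == "incr") return(stage_plan(s1, s2))
  fc <- if (preset == "incr_fc1") "FC1" else "FC2"
  s3 <- stage_directive(paste0("ff_sa_star_", tolower(fc)),
                        model_spec("ff_sa_star", channels_c, input_side),
                        inherit_from = list(stage = "rf_sa_star",
                                            blocks = "all_pre_readout"),
                        frozen_blocks = c("alpha1", "alpha2", "sa",
                                          "beta1", "beta2"),
                        readout_init = "center_from_ctl", fc_mode = fc)
  stage_plan(s1, s2, s3)
}

#' Run an incremental (or single-stage) training plan
#'
#' Trains each stage in order, applying weight inheritance, readout
#' expansion, and block freezing as declared. Freezing is verified
#' bit-exactly after each stage.
#'
#' @param plan A [stage_plan()] or [stage_plan_preset()].
#' @param stimuli Training images.
#' @param responses Single-neuron response vector (one per image).
#' @param config A [train_config()]; its seed also seeds each stage's
#'   initialization (offset by the stage index).
#' @return A named list (one entry per stage) of lists with `model`,
#'   `history`, `frozen_blocks`.
#' @export
run_plan <- function(plan, stimuli, responses, config = train_config()) {
  stopifnot(inherits(plan, "sacnn_plan"))
  out <- list()
  for (i in seq_along(plan)) {
    st <- plan[[i]]
    res <- tryCatch({
      frozen <- st$frozen_blocks
      if (st$readout_init == "center_from_ctl") {
        if (is.null(st$inherit_from))
          stop("center_from_ctl requires inherit_from")
        parent <- out[[st$inherit_from$stage]]$model
        ex <- expand_readout(parent, st$fc_mode)
        model <- ex$model
        frozen <- union(frozen, ex$frozen_blocks)
      } else {
        model <- assemble_model(st$spec, seed = config$seed + i - 1L)
        if (!is.null(st$inherit_from)) {
          blocks <- st$inherit_from$blocks
          if (identical(blocks, "all_pre_readout"))
            blocks <- setdiff(block_ids(model), "readout")
          model <- inherit_weights(out[[st$inherit_from$stage]]$model,
                                   model, blocks)
        }
      }
      tr <- train_model(model, stimuli, responses, config,
                        frozen_blocks = frozen)
      list(model = tr$model, history = tr$history, frozen_blocks = frozen)
    }, error = function(e)
      stop("stage '", st$stage_name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    out[[st$stage_name]] <- res
  }
  out
}
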