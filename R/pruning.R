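# Hidden-layer pruning: score each layer by the mean absolute weight of its
# tensor, remove eligible residual blocks whose score falls below the
# threshold (the skip path routes around a removed block, so removing an
# all-zero block leaves the forward function pointwise identical), then
# recover accuracy with transfer fine-tuning at the reduced learning rate.

#' Pruning configuration
#'
#' @param threshold Score threshold `tau` (> 0): eligible layers with mean
#'   absolute weight below it are removed.
#' @param protected Sections never pruned; the head is always protected.
#' @param max_layers_removed Cap on the number of layers removed per call.
#' @param finetune_epochs Epochs of post-prune transfer fine-tuning.
#' @param finetune_lr Fine-tuning learning rate (0.0032, the transfer
#'   schedule's reduced rate).
#' @export
prune_config <- function(threshold = 1e-3, protected = "head",
                         max_layers_removed = Inf, finetune_epochs = 2,
                         finetune_lr = 0.0032) {
  stopifnot(threshold > 0)
  protected <- union(protected, "head")
  structure(list(threshold = threshold, protected = protected,
                 max_layers_removed = max_layers_removed,
                 finetune_epochs = finetune_epochs,
                 finetune_lr = finetune_lr), class = "prune_config")
}

#' Score layers for pruning
#'
#' One score per layer: the mean absolute value of the layer's weight
#' tensor (a pure function of the weights, invariant to sign flips).
#' Eligible layers are the residual (skip-connected) blocks outside
#' protected sections.
#'
#' @param model A `layered_model`.
#' @param protected Protected sections.
#' @return data.frame with columns layer, section, score, eligible.
#' @export
score_layers <- function(model, protected = "head") {
  protected <- union(protected, "head")
  rows <- lapply(model$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    data.frame(layer = ly$name, section = ly$section,
               score = mean(abs(ly$W)),
               eligible = ly$type == "resblock" &&
                 !(ly$section %in% protected) && ly$keep)
  })
  do.call(rbind, rows)
}

#' Prune low-contribution hidden layers
#'
#' Every eligible layer whose score is below `config$threshold` has its
#' keep-flag cleared, in ascending score order (ties broken towards the
#' shallower layer), up to `max_layers_removed`. The kept parameter count
#' strictly decreases whenever a layer is removed.
#'
#' @param model A `layered_model` with at least one eligible layer.
#' @param config A [prune_config()].
#' @param force_layers Optional layer names to prune unconditionally;
#'   naming a protected-section layer is an error.
#' @return `list(model, report)`; the report lists every scored layer with
#'   columns layer, score, pruned, params_before, params_after, and carries
#'   the depth change as attribute `depth_change`.
#' @export
prune <- function(model, config = prune_config(), force_layers = NULL) {
  sc <- score_layers(model, config$protected)
  if (!any(sc$eligible)) stop("model has no eligible (prunable) layer")
  if (!is.null(force_layers)) {
    secs <- sc$section[match(force_layers, sc$layer)]
    if (anyNA(secs)) stop("unknown layer(s): ",
                          paste(force_layers[is.na(secs)], collapse = ", "))
    bad <- force_layers[secs %in% config$protected]
    if (length(bad))
      stop("cannot prune protected section layer(s): ",
           paste(bad, collapse = ", "))
  }
  params_before <- param_count(model)
  cand <- sc[sc$eligible & (sc$score < config$threshold |
                              sc$layer %in% force_layers), , drop = FALSE]
  # ascending score, earlier layer first at ties (stable order preserves it)
  cand <- cand[order(cand$score), , drop = FALSE]
  if (nrow(cand) > config$max_layers_removed)
    cand <- cand[seq_len(config$max_layers_removed), , drop = FALSE]
  if (nrow(cand) == sum(sc$eligible) && nrow(cand) > 0 &&
      config$threshold > max(sc$score[sc$eligible]))
    warning("pruning threshold exceeds every eligible score: removing ALL ",
            nrow(cand), " eligible layers")
  for (nm in cand$layer) {
    li <- which(vapply(model$layers, function(l) l$name, "") == nm)
    model$layers[[li]]$keep <- FALSE
  }
  report <- data.frame(layer = sc$layer, score = sc$score,
                       pruned = sc$layer %in% cand$layer,
                       params_before = params_before,
                       params_after = param_count(model))
  attr(report, "depth_change") <- -nrow(cand)
  list(model = model, report = report)
}

#' Transfer fine-tuning after pruning
#'
#' Freezes the backbone and retrains the remaining trainable layers at the
#' reduced learning rate (0.0032). The evaluation before and after
#' fine-tuning is recorded in the returned assessment.
#'
#' @param model A pruned `layered_model`.
#' @param shard Training data (as in [train_local()]).
#' @param config A [prune_config()].
#' @param val Optional validation data used for the before/after assessment.
#' @param seed Seed for the fine-tuning run.
#' @return `list(model, history, assessment)`.
#' @export
finetune_after_prune <- function(model, shard, config = prune_config(),
                                 val = NULL, seed = 1) {
  before <- if (!is.null(val)) evaluate(model, val)
  model <- freeze_backbone(model)
  tc <- train_config(epochs = config$finetune_epochs, lr = config$finetune_lr,
                     seed = seed)
  tr <- train_local(model, shard, tc, val = val)
  after <- if (!is.null(val)) evaluate(tr$model, val)
  list(model = tr$model, history = tr$history,
       assessment = list(before = before, after = after))
}

#' Write a prune report as CSV
#' @param report Report from [prune()].
#' @param path Output path.
#' @export
write_prune_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
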