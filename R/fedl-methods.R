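# S3 methods for fitted federated models.

#' @export
print.fedl <- function(x, ...) {
  cat("Federated two-class classifier (FedAvrg",
      if (x$config$encryption) "with encrypted aggregation)" else
        "in plaintext mode)", "\n")
  cat(sprintf("  clients: %d (sizes %s)\n", length(x$client_sizes),
              paste(x$client_sizes, collapse = "/")))
  cat(sprintf("  rounds run: %d x %d local epoch(s), batch %d, lr %g\n",
              x$rounds_run, x$config$local_epochs, x$config$batch_size,
              x$config$lr))
  g <- x$history[x$history$client_id == "global", ]
  if (nrow(g))
    cat(sprintf("  final global validation accuracy: %.4f (loss %.4f)\n",
                g$val_acc[nrow(g)], g$val_loss[nrow(g)]))
  cat(sprintf("  parameters: %d  |  key modulus: %s\n",
              length(x$global_params), x$keypair$n))
  invisible(x)
}

#' @export
summary.fedl <- function(object, ...) {
  g <- object$history[object$history$client_id == "global", ]
  cl <- object$history[object$history$client_id != "global", ]
  out <- list(
    config = object$config,
    rounds_run = object$rounds_run,
    client_sizes = object$client_sizes,
    global = g[, c("round", "val_acc", "val_loss")],
    final_val_acc = if (nrow(g)) g$val_acc[nrow(g)] else NA_real_,
    best = object$best,
    client_final = if (nrow(cl))
      cl[cl$round == max(cl$round), c("client_id", "n", "acc", "loss",
                                      "val_acc", "val_loss")]
    else cl
  )
  class(out) <- "summary.fedl"
  out
}

#' @export
print.summary.fedl <- function(x, ...) {
  cat("Federated training summary\n")
  cat(sprintf("  rounds: %d, clients: %d\n", x$rounds_run,
              length(x$client_sizes)))
  if (nrow(x$global)) {
    cat("  global validation accuracy per round:\n")
    print(x$global, row.names = FALSE)
    cat(sprintf("  best round: %d (val acc %.4f)\n", x$best$round, x$best$acc))
  }
  if (nrow(x$client_final)) {
    cat("  last-round client metrics:\n")
    print(x$client_final, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.fedl <- function(object, ...) object$global_params

#' Predict from a fitted federated model
#'
#' @param object A [fedl()] fit.
#' @param newdata An `image_set`, a `list(x = , y = )` batch, or an
#'   `N x H x W x 3` array.
#' @param type `"response"` (probabilities) or `"class"` (0/1 at 0.5).
#' @param ... Unused.
#' @export
predict.fedl <- function(object, newdata,
                         type = c("response", "class"), ...) {
  type <- match.arg(type)
  data <- if (is.array(newdata) && length(dim(newdata)) == 4)
    list(x = newdata, y = rep(0, dim(newdata)[1]))
  else as_batch(newdata)
  p <- model_predict(object$model, data)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' Plot the training trajectory of a federated fit
#'
#' Global validation accuracy per communication round, with per-client
#' validation accuracies overlaid.
#' @param x A [fedl()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fedl <- function(x, ...) {
  g <- x$history[x$history$client_id == "global", ]
  if (!nrow(g)) {
    warning("no rounds run; nothing to plot")
    return(invisible(x))
  }
  cl <- x$history[x$history$client_id != "global", ]
  ids <- unique(cl$client_id)
  graphics::plot(g$round, g$val_acc, type = "b", lwd = 2, pch = 16,
                 xlab = "communication round",
                 ylab = "validation accuracy",
                 ylim = range(c(g$val_acc, cl$val_acc), na.rm = TRUE), ...)
  for (j in seq_along(ids)) {
    ci <- cl[cl$client_id == ids[j], ]
    graphics::lines(ci$round, ci$val_acc, col = j + 1, lty = 2)
  }
  graphics::legend("bottomright", legend = c("global", paste("client", ids)),
                   col = c(1, seq_along(ids) + 1),
                   lty = c(1, rep(2, length(ids))), lwd = c(2, rep(1,
                                                                   length(ids))),
                   bty = "n", cex = 0.8)
  invisible(x)
}
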