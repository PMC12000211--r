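#' Generate a simulated training corpus
#'
#' Simulates artificial participants, summarizes each into the fixed
#' feature layout, and pairs the features with either a model label
#' (classification: 0 = diffusion, 1 = accumulator, balanced halves with
#' the \eqn{\sqrt{2}} drift scaling applied to the diffusion class) or the
#' log-transformed generative parameters (estimation: the option angle is
#' drawn from its U(0, \eqn{\pi}) prior). Participants whose trials are
#' all censored are resampled and counted. Single-condition corpora use
#' the 15-input layout; corpora simulated over a design use the 8-slots-
#' per-condition layout (96 inputs for the application design).
#'
#' @param mode \code{"classify"} or \code{"estimate"}.
#' @param n_sims Simulated participants (per class for classification).
#' @param n_trials Trials per participant (single-condition corpora).
#' @param design Optional [design_spec()]; when supplied, each participant
#'   is simulated over the full design with condition-wise parameters
#'   drawn by [sample_application_parameters()].
#' @param prior A [prior_spec()].
#' @param dt,t_max Simulation settings.
#' @param seed Optional seed; the corpus is reproducible from it.
#' @return A list of class \code{"training_set"}: \code{inputs} (matrix,
#'   one row per participant), \code{targets} (0/1 vector or log-parameter
#'   matrix), \code{params} (generative parameters), \code{mode},
#'   \code{layout}, \code{design}, \code{n_resampled}.
#' @export
generate_training_set <- function(mode = c("classify", "estimate"),
                                  n_sims, n_trials = 100, design = NULL,
                                  prior = prior_spec(), dt = 0.001,
                                  t_max = 10, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_sims >= 2)
  with_seed(seed, {
    if (mode == "classify") {
      classes <- rep(c("diffusion", "accumulator"), each = n_sims)
      labels <- rep(c(0, 1), each = n_sims)
    } else {
      classes <- rep("gsr", n_sims)
      labels <- NULL
    }
    n_total <- length(classes)
    resampled <- 0L
    rows <- vector("list", n_total)
    par_rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      repeat {
        if (is.null(design)) {
          par <- sample_parameters(1, classes[i], prior = prior)
          raw <- simulate_raw(as.list(par), n_trials, dt, t_max)
          keep <- !raw$censored
          if (!any(keep)) { resampled <- resampled + 1L; next }
          s <- summary15(raw$rt[keep], raw$correct[keep])
          rows[[i]] <- s$values
          par_rows[[i]] <- par
        } else {
          base <- sample_application_parameters(classes[i], design,
                                                prior = prior,
                                                with_s_v =
                                                  mode == "estimate")
          cm <- build_condition_parameters(base, design)
          trials <- simulate_dataset(cm, dt = dt, t_max = t_max)
          ok <- !trials$censored
          if (!all(cm$condition %in% trials$condition[ok])) {
            resampled <- resampled + 1L
            next
          }
          rows[[i]] <- as.numeric(summarize_design(trials, design))
          par_rows[[i]] <- application_target_vector(base)
        }
        break
      }
    }
    inputs <- do.call(rbind, rows)
    if (is.null(design)) colnames(inputs) <- summary15_names()
    if (mode == "classify") {
      targets <- labels
      params <- if (is.null(design)) do.call(rbind, par_rows) else
        do.call(rbind, par_rows)
    } else {
      params <- do.call(rbind, par_rows)
      tn <- if (is.null(design)) {
        c("phi", "mu_mag", "theta", "tau", "nu", "gamma")
      } else colnames(params)
      pm <- if (is.null(design)) {
        as.matrix(params[, tn])
      } else params
      targets <- log(pm)
      colnames(targets) <- tn
    }
    structure(list(inputs = inputs, targets = targets, params = params,
                   mode = mode,
                   layout = if (is.null(design)) "single15" else "design",
                   design = design, n_trials = n_trials,
                   n_resampled = resampled, seed = seed),
              class = "training_set")
  })
}

# Flatten an application-model base parameter list into the named
# 14-parameter vector used as estimation targets.
application_target_vector <- function(base) {
  v <- c(stats::setNames(base$phi, paste0("phi_m", seq_along(base$phi))),
         stats::setNames(as.vector(base$mu_mag),
                         paste0("mu_", outer(seq_len(nrow(base$mu_mag)),
                                             seq_len(ncol(base$mu_mag)),
                                             function(i, j)
                                               paste0("c", i, "m", j)))),
         stats::setNames(base$theta, paste0("theta_d", seq_along(base$theta))),
         stats::setNames(base$gamma, paste0("gamma_d", seq_along(base$gamma))),
         tau = base$tau, nu = base$nu, s_v = base$s_v)
  v
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> mode = %s, %d participants, %d inputs (%s)\n",
              x$mode, nrow(x$inputs), ncol(x$inputs), x$layout))
  invisible(x)
}

standardize_inputs <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Train the model-classification network
#'
#' Fits a feed-forward network with a probabilistic (0--1) output to the
#' summary vectors: the output approximates the posterior probability that
#' the data came from an accumulator model, with the training corpus
#' acting as the prior. Inputs are standardized by training-set mean/SD
#' (stored with the model); a held-out validation split is set aside and
#' its accuracy reported. The network is a single-hidden-layer perceptron
#' (BFGS with weight decay for regularization); the hidden size and decay
#' are configurable.
#'
#' @param train A classification [generate_training_set()].
#' @param hidden Hidden units.
#' @param decay Weight decay.
#' @param maxit Optimizer iterations.
#' @param val_frac Validation fraction held out for reporting.
#' @param seed Optional seed (weight initialization and split).
#' @return A \code{"gsr_classifier"}: the fitted net plus input
#'   standardization, layout, validation indices and accuracy.
#' @export
train_classifier <- function(train, hidden = 40, decay = 1e-3,
                             maxit = 300, val_frac = 0.1, seed = NULL) {
  stopifnot(inherits(train, "training_set"),
            identical(train$mode, "classify"))
  x <- train$inputs
  y <- train$targets
  if (any(!is.finite(x))) stop("non-finite inputs after imputation")
  with_seed(seed, {
    n <- nrow(x)
    val <- sample.int(n, max(1L, round(val_frac * n)))
    std <- standardize_inputs(x[-val, , drop = FALSE])
    net <- nnet::nnet(std$x, y[-val], size = hidden, decay = decay,
                      maxit = maxit, entropy = TRUE, trace = FALSE,
                      MaxNWts = 50000)
    model <- structure(list(net = net, center = std$center,
                            scale = std$scale, layout = train$layout,
                            n_inputs = ncol(x)),
                       class = "gsr_classifier")
    pv <- classify(model, x[val, , drop = FALSE])
    model$validation <- list(idx = val,
                             accuracy = mean((pv > 0.5) == (y[val] == 1)))
    model
  })
}

#' Posterior probability of the accumulator model
#'
#' Forward pass of a trained classifier: returns, for each summary
#' vector, the posterior probability that the generating model was the
#' accumulator (absolute-evidence) model; the diffusion probability is
#' its complement.
#'
#' @param model A [train_classifier()] result.
#' @param summary A summary vector or a matrix of summary rows matching
#'   the training layout.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
classify <- function(model, summary) {
  stopifnot(inherits(model, "gsr_classifier"))
  x <- if (is.matrix(summary)) summary else matrix(summary, nrow = 1)
  if (ncol(x) != model$n_inputs) {
    stop("summary layout mismatch: expected ", model$n_inputs,
         " inputs, got ", ncol(x))
  }
  xs <- standardize_inputs(x, model$center, model$scale)$x
  p <- as.vector(predict(model$net, xs))
  pmin(pmax(p, 0), 1)
}

#' Evaluate a classifier on held-out data
#'
#' Proportion of test participants whose posterior falls on the correct
#' side of the threshold, plus the full 2x2 confusion matrix (rows = true
#' model, columns = recovered model, rows sum to 1).
#'
#' @param model A [train_classifier()] result.
#' @param test A classification [generate_training_set()] disjoint from
#'   the training rows.
#' @param threshold Decision threshold on the accumulator posterior.
#' @return List with \code{accuracy} and \code{confusion}.
#' @export
evaluate_classifier <- function(model, test, threshold = 0.5) {
  stopifnot(inherits(test, "training_set"),
            identical(test$mode, "classify"))
  if (!nrow(test$inputs)) stop("empty test set")
  p <- classify(model, test$inputs)
  pred <- ifelse(p > threshold, 1, 0)
  truth <- test$targets
  conf <- matrix(0, 2, 2,
                 dimnames = list(true = c("diffusion", "accumulator"),
                                 recovered = c("diffusion", "accumulator")))
  for (tm in 0:1) {
    idx <- truth == tm
    if (!any(idx)) stop("test set lacks class ", tm)
    conf[tm + 1, ] <- c(mean(pred[idx] == 0), mean(pred[idx] == 1))
  }
  list(accuracy = mean(pred == truth), confusion = conf)
}

#' Train the parameter-estimation network
#'
#' Fits a multi-output regression network from summary vectors to the
#' log-transformed generative parameters (log outputs guarantee positive
#' parameter estimates after inversion). Single-condition corpora have 6
#' outputs (the five generative parameters plus the option angle); the
#' application design has 14.
#'
#' @inheritParams train_classifier
#' @param train An estimation [generate_training_set()].
#' @return A \code{"gsr_estimator"} with the net, standardization and the
#'   output-parameter names.
#' @export
train_estimator <- function(train, hidden = 40, decay = 1e-3,
                            maxit = 400, val_frac = 0.1, seed = NULL) {
  stopifnot(inherits(train, "training_set"),
            identical(train$mode, "estimate"))
  x <- train$inputs
  y <- train$targets
  if (any(!is.finite(x))) stop("non-finite inputs after imputation")
  with_seed(seed, {
    n <- nrow(x)
    val <- sample.int(n, max(1L, round(val_frac * n)))
    std <- standardize_inputs(x[-val, , drop = FALSE])
    ystd <- standardize_inputs(y[-val, , drop = FALSE])
    net <- nnet::nnet(std$x, ystd$x, size = hidden, decay = decay,
                      maxit = maxit, linout = TRUE, trace = FALSE,
                      MaxNWts = 50000)
    structure(list(net = net, center = std$center, scale = std$scale,
                   y_center = ystd$center, y_scale = ystd$scale,
                   parameters = colnames(y), layout = train$layout,
                   n_inputs = ncol(x), validation_idx = val),
              class = "gsr_estimator")
  })
}

#' Estimate generative parameters from a summary vector
#'
#' Forward pass of a trained estimator; network outputs are mapped back
#' from the log scale by exponentiation, so all estimates are strictly
#' positive. Option-angle estimates are clipped to \eqn{(0, \pi]}.
#'
#' @param model A [train_estimator()] result.
#' @param summary Summary vector or matrix of rows.
#' @param log_scale Return log-scale estimates instead of natural scale.
#' @return Matrix of parameter estimates (rows = participants).
#' @export
estimate_parameters <- function(model, summary, log_scale = FALSE) {
  stopifnot(inherits(model, "gsr_estimator"))
  x <- if (is.matrix(summary)) summary else matrix(summary, nrow = 1)
  if (ncol(x) != model$n_inputs) {
    stop("summary layout mismatch: expected ", model$n_inputs,
         " inputs, got ", ncol(x))
  }
  xs <- standardize_inputs(x, model$center, model$scale)$x
  out <- predict(model$net, xs)
  out <- sweep(sweep(out, 2, model$y_scale, "*"), 2, model$y_center, "+")
  colnames(out) <- model$parameters
  if (log_scale) return(out)
  est <- exp(out)
  gcol <- grep("^gamma", colnames(est))
  est[, gcol] <- pmin(est[, gcol], pi)
  est
}

#' Parameter-recovery report
#'
#' Per-parameter linear correlation between true and estimated values and
#' root-mean-square error on the log scale, split by training/validation
#' label.
#'
#' @param true,estimated Matrices of matching shape (natural scale).
#' @param split Optional factor of split labels per row (e.g. "training"
#'   / "validation").
#' @return A data.frame of class \code{"recovery_report"} with columns
#'   \code{parameter}, \code{split}, \code{r}, \code{rmse_log}.
#' @export
recovery_report <- function(true, estimated, split = NULL) {
  true <- as.matrix(true)
  estimated <- as.matrix(estimated)
  if (!all(dim(true) == dim(estimated))) stop("shape mismatch")
  if (is.null(split)) split <- rep("all", nrow(true))
  stopifnot(length(split) == nrow(true))
  out <- do.call(rbind, lapply(unique(split), function(sp) {
    idx <- split == sp
    do.call(rbind, lapply(seq_len(ncol(true)), function(j) {
      tv <- true[idx, j]
      ev <- estimated[idx, j]
      data.frame(parameter = if (is.null(colnames(true))) paste0("p", j)
                 else colnames(true)[j],
                 split = sp,
                 r = if (sd(tv) > 0 && sd(ev) > 0) cor(tv, ev) else NA_real_,
                 rmse_log = sqrt(mean((log(tv) - log(ev))^2)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("recovery_report", "data.frame")
  out
}
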