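# The LRRGD ensemble: feature bagging, per-bag ridge logistic regression
# fitted by damped Newton steps, projected gradient-descent refinement of
# a relaxed protein-indicator vector with informed initialization,
# binarization, vote tallying and threshold selection.

#' Bag size as the rounded square root of the feature count
#'
#' The random-forest convention for the number of features per model:
#' `round(sqrt(n_features))`, at least 1 (1608 features give bags of 40).
#'
#' @param n_features Total feature count (>= 1).
#' @return Integer bag size.
#' @export
feature_subset_size <- function(n_features) {
  if (n_features < 1) stop("n_features must be >= 1")
  max(1L, as.integer(round(sqrt(n_features))))
}

#' Expected number of times a feature is selected across rounds
#'
#' Bags of `bag_size` drawn uniformly without replacement (restored
#' between rounds) select each feature `n_rounds * bag_size / n_features`
#' times in expectation (400 rounds of 40 from 1608 give about 10).
#'
#' @param n_rounds,bag_size,n_features Positive counts with
#'   `bag_size <= n_features`.
#' @return Expected selection count.
#' @export
expected_selections <- function(n_rounds, bag_size, n_features) {
  if (min(n_rounds, bag_size, n_features) < 1)
    stop("all arguments must be positive")
  if (bag_size > n_features) stop("bag_size cannot exceed n_features")
  n_rounds * bag_size / n_features
}

#' Draw one feature bag
#'
#' Uniform sample without replacement from `1:n_features` using the
#' current RNG state (which is advanced deterministically).
#'
#' @param n_features Pool size.
#' @param bag_size Bag size (<= `n_features`).
#' @return Integer vector of distinct feature indices.
#' @export
sample_features <- function(n_features, bag_size) {
  if (bag_size > n_features)
    stop("bag_size cannot exceed n_features")
  sample.int(n_features, bag_size, replace = FALSE)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.logistic_loss <- function(theta, Xd, y, lambda) {
  m <- nrow(Xd)
  h <- .sigmoid(drop(Xd %*% theta))
  h <- pmin(pmax(h, 1e-12), 1 - 1e-12)
  ce <- -mean(y * log(h) + (1 - y) * log(1 - h))
  ce + lambda / (2 * m) * sum(theta[-1]^2)
}

#' Ridge logistic regression fitted by damped Newton steps
#'
#' Minimizes the cross-entropy loss
#' `J(theta) = -(1/m) sum(y*log(h) + (1-y)*log(1-h)) +
#'  (lambda/2m)*||theta[-intercept]||^2` with `h = sigmoid(X theta)`.
#' Fractional labels in `[0, 1]` are accepted (the loss is a proper
#' scoring rule there, and the labels here are normalized similarities,
#' not classes). Each Newton step is halved until the penalized loss does
#' not increase; the intercept is unpenalized.
#'
#' @param X_bag Numeric samples-by-features matrix (no intercept column;
#'   column names are the bag's protein accessions).
#' @param y Labels in `[0, 1]`, one per row.
#' @param ridge Penalty `lambda >= 0` (default 1); `lambda > 0` is
#'   required whenever the Hessian would otherwise be singular
#'   (more features than samples).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence threshold on the step norm.
#' @return A `logistic_model`: list with `theta` (intercept first),
#'   `feature_ids`, `converged`, `final_loss`, `n_iter`.
#' @export
fit_logistic_newton <- function(X_bag, y, ridge = 1, max_iter = 50,
                                tol = 1e-8) {
  X_bag <- as.matrix(X_bag)
  if (nrow(X_bag) != length(y))
    stop("row count of X_bag must equal length of y")
  if (!ncol(X_bag)) stop("empty feature bag")
  if (!all(is.finite(X_bag)) || !all(is.finite(y)))
    stop("non-finite entries in X_bag or y")
  if (any(y < 0 | y > 1)) stop("labels must lie in [0, 1]")
  if (ridge < 0) stop("ridge penalty must be >= 0")

  m <- nrow(X_bag)
  Xd <- cbind(`(intercept)` = 1, X_bag)
  p <- ncol(Xd)
  pen_mask <- c(0, rep(1, p - 1))  # intercept unpenalized
  theta <- numeric(p)
  loss <- .logistic_loss(theta, Xd, y, ridge)
  converged <- FALSE
  it <- 0

  for (it in seq_len(max_iter)) {
    h <- .sigmoid(drop(Xd %*% theta))
    grad <- drop(crossprod(Xd, h - y)) / m + (ridge / m) * pen_mask * theta
    w <- h * (1 - h)
    H <- crossprod(Xd, Xd * w) / m + (ridge / m) * diag(pen_mask, p)
    step <- tryCatch(solve(H, grad), error = function(e) {
      if (ridge == 0)
        stop("singular Hessian; refit with a ridge penalty lambda > 0",
             call. = FALSE)
      stop("Newton step failed: ", conditionMessage(e), call. = FALSE)
    })
    # damping: halve until the penalized loss does not increase
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      cand_loss <- .logistic_loss(cand, Xd, y, ridge)
      if (cand_loss <= loss + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- cand
    loss <- cand_loss
    if (sqrt(sum((alpha * step)^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(theta = stats::setNames(theta, colnames(Xd)),
                 feature_ids = colnames(X_bag),
                 converged = converged, final_loss = loss, n_iter = it),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model:", length(x$feature_ids), "features, loss",
      format(x$final_loss, digits = 4),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Refine a relaxed protein-indicator vector by projected gradient descent
#'
#' Starting from a 0/1 initialization (1 for bag proteins in the known
#' seed set), minimizes `f(x) = (h_theta(x) - 1)^2` — the squared gap
#' between the model's predicted similarity and the target's
#' self-similarity of 1 — by gradient descent with projection of every
#' coordinate onto `[0, 1]` after each step. Iteration stops when the
#' absolute loss change drops below `tol` or `max_iter` is reached. The
#' relaxed vector is binarized at 0.5: the 1-entries are the proteins the
#' model calls related.
#'
#' @param model A `logistic_model`.
#' @param x_init Numeric vector in `[0, 1]` over the bag's features.
#' @param step Descent rate `k > 0` (default 0.1).
#' @param tol Stopping threshold `epsilon` on `|f_{n+1} - f_n|`
#'   (default 1e-3, i.e. 0.1 percent of the loss's `[0, 1]` range).
#'   The refinement is a local search around the informed
#'   initialization: a tolerance loose relative to the loss range stops
#'   it once per-iteration progress is negligible, while a very tight
#'   tolerance would run every coordinate to the saturated bound
#'   matching its weight's sign, erasing both the initialization and the
#'   weight magnitudes the call is meant to reflect.
#' @param max_iter Iteration cap (default 10000).
#' @return An `indicator_vector`: list with `values` (relaxed, in
#'   `[0, 1]`), `binarized` (integer 0/1, threshold 0.5), `iterations`,
#'   `f_final`.
#' @export
gd_refine_indicator <- function(model, x_init, step = 0.1, tol = 1e-3,
                                max_iter = 10000) {
  stopifnot(inherits(model, "logistic_model"))
  if (step <= 0) stop("step must be positive")
  if (tol <= 0) stop("tol must be positive")
  w <- unname(model$theta[-1])
  b <- unname(model$theta[[1]])
  if (length(x_init) != length(w))
    stop("x_init length must equal the bag size")
  if (any(x_init < 0 | x_init > 1)) stop("x_init must lie in [0, 1]")

  x <- as.numeric(x_init)
  fval <- function(x) (.sigmoid(b + sum(w * x)) - 1)^2
  f_old <- fval(x)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    h <- .sigmoid(b + sum(w * x))
    grad <- 2 * (h - 1) * h * (1 - h) * w
    x <- pmin(1, pmax(0, x - step * grad))
    f_new <- fval(x)
    if (abs(f_new - f_old) < tol) {
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  structure(list(values = x, binarized = as.integer(x >= 0.5),
                 iterations = it, f_final = f_old),
            class = "indicator_vector")
}

#' @export
print.indicator_vector <- function(x, ...) {
  cat("indicator_vector:", sum(x$binarized), "of", length(x$values),
      "coordinates called after", x$iterations, "iterations\n")
  invisible(x)
}

#' Run the bagged logistic-regression / gradient-descent ensemble
#'
#' For each round: draw a feature bag, fit a ridge logistic regression of
#' the normalized similarity labels on the bagged binary features over
#' all disease rows, refine the target disease's relaxed indicator vector
#' by projected gradient descent from the known-protein initialization,
#' binarize at 0.5, and tally. Every bag protein gains one
#' `times_selected`; those binarized to 1 gain one `times_called_related`.
#' Rounds whose fit fails still count toward `times_selected` (with a
#' warning) so the tally denominator stays honest. The run is a pure
#' function of its inputs and `rng_seed`; per-round RNG substreams are
#' derived from the master seed so results do not depend on execution
#' order.
#'
#' @param fm A `feature_matrix`.
#' @param target_row Disease id of the target (must be a row of `fm`).
#' @param seed_proteins Accessions of known target-related proteins used
#'   as the informed initialization; accessions absent from the matrix
#'   are ignored with a warning.
#' @param n_rounds Ensemble rounds (default 400).
#' @param bag_size Features per bag; default
#'   `feature_subset_size(ncol(X))`.
#' @param rng_seed Master seed.
#' @param ridge Ridge penalty for the per-bag fits (default 1).
#' @param gd_step,gd_tol,gd_max_iter Gradient-descent controls passed to
#'   [gd_refine_indicator()].
#' @param newton_max_iter,newton_tol Newton controls passed to
#'   [fit_logistic_newton()].
#' @return A `vote_tally`: data.frame with `protein_accession`,
#'   `times_selected`, `times_called_related`, plus attributes
#'   `n_rounds`, `bag_size`, `rng_seed`, `failed_rounds`, `seed_proteins`.
#' @export
run_ensemble <- function(fm, target_row, seed_proteins = character(),
                         n_rounds = 400, bag_size = NULL, rng_seed = 1,
                         ridge = 1, gd_step = 0.1, gd_tol = 1e-3,
                         gd_max_iter = 10000, newton_max_iter = 50,
                         newton_tol = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!target_row %in% fm$disease_index)
    stop("target disease ", target_row, " is not a row of the feature matrix")
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  p <- length(fm$protein_index)
  if (is.null(bag_size)) bag_size <- feature_subset_size(p)
  if (bag_size < 1 || bag_size > p)
    stop("bag_size must lie in [1, number of proteins]")

  unknown_seeds <- setdiff(seed_proteins, fm$protein_index)
  if (length(unknown_seeds)) {
    warning("ignoring ", length(unknown_seeds),
            " seed protein(s) absent from the matrix")
    seed_proteins <- setdiff(seed_proteins, unknown_seeds)
  }
  is_seed <- fm$protein_index %in% seed_proteins

  X <- fm$X
  storage.mode(X) <- "double"
  y <- fm$y

  # per-round substreams derived once from the master seed
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  round_seeds <- sample.int(.Machine$integer.max - 1L, n_rounds)

  times_selected <- integer(p)
  times_called <- integer(p)
  failed <- 0L

  for (r in seq_len(n_rounds)) {
    set.seed(round_seeds[[r]])
    bag <- sort(sample_features(p, bag_size))
    times_selected[bag] <- times_selected[bag] + 1L
    fit <- tryCatch(
      fit_logistic_newton(X[, bag, drop = FALSE], y, ridge = ridge,
                          max_iter = newton_max_iter, tol = newton_tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- failed + 1L
      warning("round ", r, " fit failed: ", conditionMessage(fit))
      next
    }
    x_init <- as.numeric(is_seed[bag])
    ind <- gd_refine_indicator(fit, x_init, step = gd_step, tol = gd_tol,
                               max_iter = gd_max_iter)
    called <- bag[ind$binarized == 1L]
    times_called[called] <- times_called[called] + 1L
  }

  tally <- data.frame(protein_accession = fm$protein_index,
                      times_selected = times_selected,
                      times_called_related = times_called,
                      stringsAsFactors = FALSE)
  structure(tally, class = c("vote_tally", "data.frame"),
            n_rounds = n_rounds, bag_size = bag_size, rng_seed = rng_seed,
            failed_rounds = failed, seed_proteins = seed_proteins)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Select related proteins by vote threshold
#'
#' @param tally A `vote_tally`.
#' @param vote_threshold Minimum `times_called_related` (inclusive,
#'   default 7).
#' @return Accessions with calls at or above the threshold, sorted by
#'   call count descending then accession.
#' @export
select_related <- function(tally, vote_threshold = 7) {
  if (vote_threshold < 0) stop("vote_threshold must be >= 0")
  hit <- tally[tally$times_called_related >= vote_threshold &
                 tally$times_selected > 0, , drop = FALSE]
  hit <- hit[order(-hit$times_called_related, hit$protein_accession), ,
             drop = FALSE]
  hit$protein_accession
}

#' Percentage of identified proteins that were already known
#'
#' @param n_identified Total proteins selected by the ensemble.
#' @param n_novel How many of them are not in the known set
#'   (`<= n_identified`).
#' @return Known share in percent (full precision; display-round to
#'   integer), e.g. 376 identified with 308 novel gives about 18.
#' @export
known_fraction <- function(n_identified, n_novel) {
  if (n_identified == 0) stop("n_identified must be positive")
  if (n_novel > n_identified || n_novel < 0)
    stop("n_novel must lie in [0, n_identified]")
  100 * (n_identified - n_novel) / n_identified
}
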