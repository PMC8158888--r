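#' Training configuration
#'
#' Defaults are the reference training regime: Adam, learning rate 1e-5,
#' batch size 1, 30 epochs, 10% of training slices held out for validation,
#' the >100-pixel foreground filter for coarse-stage slices, and 4-fold
#' cross-validation.
#'
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size Slices per optimizer step (>= 1).
#' @param val_fraction Fraction of training slices used for validation.
#' @param min_pancreas_pixels Strict foreground-pixel threshold for
#'   coarse-stage slice selection.
#' @param seed Integer seed controlling shuffling, splits and weight init.
#' @param folds Folds for [cross_validate].
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, learning_rate = 1e-5, batch_size = 1L,
                         val_fraction = 0.10, min_pancreas_pixels = 100L,
                         seed = 1L, folds = 4L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            val_fraction > 0, val_fraction < 1, folds >= 1L)
  structure(list(epochs = as.integer(epochs), optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 min_pancreas_pixels = as.integer(min_pancreas_pixels),
                 seed = as.integer(seed), folds = as.integer(folds)),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

.adam_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list()
  st$v <- list()
  st$t <- 0L
  st
}

.adam_step <- function(P, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- if (is.null(state$m[[nm]])) g * (1 - beta1) else
      beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- if (is.null(state$v[[nm]])) g * g * (1 - beta2) else
      beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    p <- get(nm, envir = P, inherits = FALSE)
    assign(nm, p - lr * (m / c1) / (sqrt(v / c2) + eps), envir = P)
  }
  invisible(state)
}

# ---- data preparation ------------------------------------------------------

.check_cases <- function(cases) {
  stopifnot(is.list(cases), length(cases) >= 1L)
  for (cs in cases) {
    if (!all(c("image", "mask") %in% names(cs))) {
      stop("each case must be a list(image=, mask=)")
    }
    if (!all(dim(cs$image$data) == dim(cs$mask$data))) {
      stop("image/mask shape mismatch in a case")
    }
  }
  cases
}

# Build per-case network-resolution slice stacks and the eligible slice list.
.prep_view <- function(cases, axis, insz, stage, min_pixels) {
  rimg <- vector("list", length(cases))
  rmsk <- vector("list", length(cases))
  samples <- NULL
  for (ci in seq_along(cases)) {
    istack <- extract_slices(cases[[ci]]$image, axis)
    mstack <- extract_slices(cases[[ci]]$mask, axis)
    keep <- if (stage == "coarse") {
      filter_training_slices(istack, mstack, min_pixels)
    } else {
      filter_training_slices(istack, mstack, 0L)  # any foreground
    }
    istack$slices <- lapply(istack$slices, resize_slice, target = insz,
                            is_mask = FALSE)
    mstack$slices <- lapply(mstack$slices, resize_slice, target = insz,
                            is_mask = TRUE)
    rimg[[ci]] <- istack
    rmsk[[ci]] <- mstack
    if (length(keep)) {
      samples <- rbind(samples, data.frame(case = ci, idx = keep))
    }
  }
  list(rimg = rimg, rmsk = rmsk, samples = samples)
}

#' Train one per-view model
#'
#' Extracts slices along `axis`, keeps coarse-stage slices with strictly
#' more than `min_pancreas_pixels` foreground pixels (fine stage: any
#' foreground), builds the 3-adjacent-slice 2.5D input for each kept slice,
#' holds out `val_fraction` of the slices for validation, and minimizes the
#' soft Dice loss with Adam. Fully reproducible from `cfg$seed`.
#'
#' @param cases List of `list(image = volume, mask = volume)` (>= 1; for the
#'   fine stage these are pre-cropped blocks).
#' @param axis View name (`"sagittal"`, `"coronal"`, `"axial"`).
#' @param cfg A [train_config].
#' @param model_cfg A [model_config].
#' @param stage `"coarse"` or `"fine"` (controls the slice filter).
#' @return List with the trained `model` and a `history` data frame of
#'   per-epoch train/validation Dice loss.
#' @export
train_stage <- function(cases, axis, cfg = train_config(),
                        model_cfg = model_config(),
                        stage = c("coarse", "fine")) {
  stage <- match.arg(stage)
  cases <- .check_cases(cases)
  set.seed(cfg$seed)
  prep <- .prep_view(cases, axis, model_cfg$in_size, stage,
                     cfg$min_pancreas_pixels)
  if (is.null(prep$samples) || nrow(prep$samples) == 0L) {
    stop("no qualifying training slices on the ", axis, " axis")
  }
  n <- nrow(prep$samples)
  ord <- sample.int(n)
  n_val <- max(1L, round(cfg$val_fraction * n))
  if (n_val >= n) stop("too few slices to hold out a validation set")
  val_ids <- ord[seq_len(n_val)]
  train_ids <- ord[-seq_len(n_val)]

  model <- build_model(model_cfg)
  state <- .adam_new()
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  run_loss <- function(id, tape) {
    case <- prep$samples$case[id]
    idx <- prep$samples$idx[id]
    x <- make_input25d(prep$rimg[[case]], idx)
    y <- prep$rmsk[[case]]$slices[[idx]]
    out <- .forward_seg(model, x, tape)
    op_dice_loss(tape, out, y)
  }

  for (epoch in seq_len(cfg$epochs)) {
    losses <- numeric(0)
    pending <- 0L
    grad_acc <- NULL
    for (id in sample(train_ids)) {
      tape <- new_tape()
      loss <- run_loss(id, tape)
      tape_backward(tape, loss)
      g <- tape_param_grads(tape)
      grad_acc <- if (is.null(grad_acc)) g else {
        for (nm in names(g)) grad_acc[[nm]] <- grad_acc[[nm]] + g[[nm]]
        grad_acc
      }
      pending <- pending + 1L
      if (pending == cfg$batch_size) {
        if (cfg$batch_size > 1L) {
          grad_acc <- lapply(grad_acc, function(gg) gg / cfg$batch_size)
        }
        .adam_step(model$params, grad_acc, state, cfg$learning_rate)
        grad_acc <- NULL
        pending <- 0L
      }
      losses <- c(losses, loss$value)
    }
    if (pending > 0L) {
      .adam_step(model$params, lapply(grad_acc, function(gg) gg / pending),
                 state, cfg$learning_rate)
    }
    val_losses <- vapply(val_ids, function(id) run_loss(id, NULL)$value,
                         numeric(1))
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = mean(losses),
                                val_loss = mean(val_losses)))
  }
  list(model = model, history = history,
       n_train = length(train_ids), n_val = n_val)
}

# ---- cascade-level training & evaluation -----------------------------------

.crop_case <- function(case, margin) {
  box <- coarse_bbox(case$mask, margin = margin)
  list(image = crop_volume(case$image, box), mask = crop_volume(case$mask, box))
}

#' Train the full coarse-to-fine model set
#'
#' Trains three coarse per-view models on the full volumes, then three fine
#' models on blocks cropped around the ground-truth masks with the safety
#' margin (the standard cascade practice when coarse predictions are not yet
#' available at training time). Each of the six runs gets a distinct seed
#' derived from `cfg$seed`.
#'
#' @param cases Training cases (`list(image=, mask=)`).
#' @param cfg A [train_config].
#' @param model_cfg A [model_config].
#' @param margin Crop frame width in voxels.
#' @param fine_cfg Optional [train_config] for the fine stage (defaults to
#'   `cfg`; fine-stage models typically converge in fewer epochs because the
#'   organ dominates the crop).
#' @param fine_model_cfg Optional [model_config] for the fine stage
#'   (defaults to `model_cfg`; crops are smaller than full slices, so a
#'   smaller input size loses little detail).
#' @return List with named model lists `coarse` and `fine` and the per-run
#'   training histories.
#' @export
train_cascade <- function(cases, cfg = train_config(),
                          model_cfg = model_config(), margin = 20L,
                          fine_cfg = cfg, fine_model_cfg = model_cfg) {
  cases <- .check_cases(cases)
  histories <- list()
  coarse <- list()
  for (k in seq_along(VIEW_NAMES)) {
    ax <- VIEW_NAMES[k]
    ck <- cfg
    ck$seed <- cfg$seed + k
    r <- train_stage(cases, ax, ck, model_cfg, stage = "coarse")
    coarse[[ax]] <- r$model
    histories[[paste0("coarse_", ax)]] <- r$history
  }
  cropped <- lapply(cases, .crop_case, margin = margin)
  fine <- list()
  for (k in seq_along(VIEW_NAMES)) {
    ax <- VIEW_NAMES[k]
    ck <- fine_cfg
    ck$seed <- cfg$seed + 10L + k
    r <- train_stage(cropped, ax, ck, fine_model_cfg, stage = "fine")
    fine[[ax]] <- r$model
    histories[[paste0("fine_", ax)]] <- r$history
  }
  list(coarse = coarse, fine = fine, histories = histories)
}

#' Evaluate fused single-stage predictions
#'
#' @param models Named per-view model list.
#' @param cases Test cases.
#' @param vote_threshold Majority-vote fraction.
#' @return Numeric vector of per-case volume DSC.
#' @export
evaluate_fused <- function(models, cases, vote_threshold = 0.5) {
  vapply(cases, function(cs) {
    dsc(.predict_fused(.check_views(models), cs$image, vote_threshold), cs$mask)
  }, numeric(1))
}

#' Evaluate the full cascade
#'
#' @param coarse_models,fine_models Named per-view model lists.
#' @param cases Test cases.
#' @param margin,vote_threshold Cascade parameters.
#' @return Numeric vector of per-case volume DSC.
#' @export
evaluate_pipeline <- function(coarse_models, fine_models, cases,
                              margin = 20L, vote_threshold = 0.5) {
  vapply(cases, function(cs) {
    pred <- run_pipeline(cs$image, coarse_models, fine_models,
                         margin = margin, vote_threshold = vote_threshold)
    dsc(pred, cs$mask)
  }, numeric(1))
}

#' Deterministic fold assignment
#'
#' Shuffles case indices with `seed` and deals them round-robin, so fold
#' sizes differ by at most one.
#'
#' @param n Number of cases.
#' @param folds Number of folds (`<= n`).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..folds), one per case.
#' @export
assign_folds <- function(n, folds, seed = 1L) {
  if (folds > n) stop("more folds than cases")
  set.seed(seed)
  ord <- sample.int(n)
  labels <- integer(n)
  labels[ord] <- rep(seq_len(folds), length.out = n)
  labels
}

#' k-fold cross-validation of the segmentation pipeline
#'
#' Splits the cases into `cfg$folds` deterministic folds, trains on the
#' remaining folds and tests on each held-out fold exactly once.
#'
#' @param cases Dataset (`list(image=, mask=)` per case; `length >= folds`).
#' @param cfg A [train_config].
#' @param model_cfg A [model_config].
#' @param stage `"coarse"` (fused coarse predictions) or `"full"` (the whole
#'   cascade).
#' @param margin,vote_threshold Cascade parameters.
#' @return List with `fold_summaries` (per-fold `score_summary`), `pooled`
#'   (over all cases), per-case `scores`, and the fold `assignment`.
#' @export
cross_validate <- function(cases, cfg = train_config(),
                           model_cfg = model_config(),
                           stage = c("coarse", "full"),
                           margin = 20L, vote_threshold = 0.5) {
  stage <- match.arg(stage)
  cases <- .check_cases(cases)
  assignment <- assign_folds(length(cases), cfg$folds, cfg$seed)
  scores <- numeric(length(cases))
  fold_summaries <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    test_idx <- which(assignment == f)
    train_cases <- cases[assignment != f]
    ck <- cfg
    ck$seed <- cfg$seed + 100L * f
    if (stage == "coarse") {
      coarse <- list()
      for (k in seq_along(VIEW_NAMES)) {
        cv <- ck
        cv$seed <- ck$seed + k
        coarse[[VIEW_NAMES[k]]] <-
          train_stage(train_cases, VIEW_NAMES[k], cv, model_cfg, "coarse")$model
      }
      s <- evaluate_fused(coarse, cases[test_idx], vote_threshold)
    } else {
      tc <- train_cascade(train_cases, ck, model_cfg, margin = margin)
      s <- evaluate_pipeline(tc$coarse, tc$fine, cases[test_idx],
                             margin = margin, vote_threshold = vote_threshold)
    }
    scores[test_idx] <- s
    fold_summaries[[f]] <- summarize_scores(s)
  }
  list(fold_summaries = fold_summaries, pooled = summarize_scores(scores),
       scores = scores, assignment = assignment)
}
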