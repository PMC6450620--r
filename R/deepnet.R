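# Map from row-major valid-cell order (s01..s54) to the column-major
# position (1..72) of the flattened 8x9 grid, per eye.
map54to72 <- function(eye) {
  m <- hvf_mask(eye)
  ti <- which(t(m)) - 1L            # row-major linear index
  r <- ti %/% 9L + 1L
  c <- ti %% 9L + 1L
  (c - 1L) * 8L + r
}

mask72 <- function(eye) {
  as.numeric(as.vector(hvf_mask(eye)))
}

COVARIATE_ORDER <- c("age", "gender", "eye", "test_number")
CATEGORICAL_COVARIATES <- c("gender", "eye")

#' Input-channel arithmetic for covariate encodings
#'
#' The base input is the sensitivity grid (one channel). Each continuous
#' covariate (`age`, `test_number`) adds one constant-valued channel; each
#' categorical covariate (`gender`, `eye`, both binary) adds a one-hot pair
#' of channels.
#'
#' @param covariates Character subset of
#'   `c("age", "gender", "eye", "test_number")`.
#' @return Integer channel count.
#' @examples
#' n_input_channels(character())      # 1
#' n_input_channels(c("age", "eye"))  # 4
#' @export
n_input_channels <- function(covariates = character()) {
  stopifnot(all(covariates %in% COVARIATE_ORDER))
  1L + sum(!covariates %in% CATEGORICAL_COVARIATES) +
    2L * sum(covariates %in% CATEGORICAL_COVARIATES)
}

# Batch encoder: field rows -> (N*72) x C activation matrix. Face order is
# fixed: sensitivities, then age, gender (male, female), eye (right, left),
# test_number, keeping only requested covariates.
encode_batch <- function(fields, covariates = character(),
                         age_div100 = FALSE) {
  stopifnot(all(covariates %in% COVARIATE_ORDER))
  n <- nrow(fields)
  sv <- field_matrix(fields)
  A <- matrix(0, n * NPOS, n_input_channels(covariates))
  pos_r <- map54to72("right")
  pos_l <- map54to72("left")
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * NPOS + 1L):(i * NPOS)
    pos <- if (fields$eye[i] == "right") pos_r else pos_l
    v72 <- numeric(NPOS)
    v72[pos] <- sv[i, ]
    A[rows, 1L] <- v72
    ch <- 1L
    for (cv in COVARIATE_ORDER) {
      if (!cv %in% covariates) next
      if (cv == "age") {
        a <- fields$age_years[i]
        if (age_div100) a <- a / 100
        A[rows, ch + 1L] <- a
        ch <- ch + 1L
      } else if (cv == "gender") {
        A[rows, ch + 1L] <- as.numeric(fields$gender[i] == "male")
        A[rows, ch + 2L] <- as.numeric(fields$gender[i] == "female")
        ch <- ch + 2L
      } else if (cv == "eye") {
        A[rows, ch + 1L] <- as.numeric(fields$eye[i] == "right")
        A[rows, ch + 2L] <- as.numeric(fields$eye[i] == "left")
        ch <- ch + 2L
      } else {
        A[rows, ch + 1L] <- fields$test_number[i]
        ch <- ch + 1L
      }
    }
  }
  A
}

#' Encode one field record as an input tensor
#'
#' Builds the C x 8 x 9 input tensor for a single test: the masked
#' sensitivity grid (invalid cells 0) plus one constant-valued channel per
#' continuous covariate and a one-hot channel pair per categorical
#' covariate, in the fixed order age, gender, eye, test number.
#'
#' @param record A one-row field tibble.
#' @param covariates Subset of `c("age", "gender", "eye", "test_number")`.
#' @param age_div100 Scale the age channel by 1/100 (off by default; ages
#'   are encoded in raw years).
#' @return A numeric array of dimension `c(C, 8, 9)`.
#' @export
encode_input <- function(record, covariates = character(),
                         age_div100 = FALSE) {
  stopifnot(nrow(record) == 1L)
  if (any(covariates == "age") && !is.finite(record$age_years)) {
    abort("missing age on record.")
  }
  A <- encode_batch(record, covariates, age_div100)
  C <- ncol(A)
  out <- array(0, dim = c(C, 8L, 9L))
  for (ch in seq_len(C)) out[ch, , ] <- matrix(A[, ch], 8L, 9L)
  out
}

#' Architecture specification
#'
#' Four families of 8x9-to-8x9 regression networks, each ending in a
#' linear single-channel projection:
#' * `cascade` — k copies of a three-convolution block; every block (and
#'   the final projection) consumes the channel-concatenation of the
#'   original input and all previous block outputs (dense copy-concatenation
#'   connectivity).
#' * `residual` — k blocks with an additive skip around each block (1x1
#'   projection when channel counts differ).
#' * `fullbn` — the same blocks stacked sequentially without skips.
#' * `fully_connected` — flatten, one ReLU hidden layer, linear output.
#'
#' Convolutions are 3x3, stride 1, zero-padded "same", ReLU-activated, with
#' batch normalisation after each convolution (toggleable). Filter widths
#' default to a desk-scale profile of `c(8, 16, 32)`; the full-scale
#' profile uses `c(64, 128, 256)`.
#'
#' @param family One of `"cascade"`, `"residual"`, `"fullbn"`,
#'   `"fully_connected"`.
#' @param k Number of block copies (ignored for `fully_connected`).
#' @param filters Filter counts of the three convolutions within a block.
#' @param batch_norm Use batch normalisation after each convolution.
#' @param hidden Hidden width for the fully connected family.
#' @return An object of class `arch_spec`.
#' @examples
#' arch_spec("cascade", k = 5, filters = c(64, 128, 256))
#' @export
arch_spec <- function(family = c("cascade", "residual", "fullbn",
                                 "fully_connected"),
                      k = 2L, filters = c(8L, 16L, 32L),
                      batch_norm = TRUE, hidden = 64L) {
  family <- match.arg(family)
  stopifnot(k >= 1L, all(filters > 0L), hidden > 0L)
  structure(list(family = family, k = as.integer(k),
                 filters = as.integer(filters),
                 batch_norm = isTRUE(batch_norm),
                 hidden = as.integer(hidden)),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec: %s, k = %d, filters = %s>\n", x$family, x$k,
              paste(x$filters, collapse = "/")))
  invisible(x)
}

#' Instantiate a network
#'
#' Builds the parameter structure for an [arch_spec()] with
#' Glorot-uniform (Xavier) initial weights drawn from the current RNG
#' state (seed it with `withr::with_seed()` or a [train_config()] seed for
#' reproducibility).
#'
#' @param spec An [arch_spec()].
#' @param in_channels Input channel count ([n_input_channels()]).
#' @return An object of class `hvf_net`.
#' @export
build_model <- function(spec, in_channels = 1L) {
  stopifnot(inherits(spec, "arch_spec"), in_channels >= 1L)
  model <- list(spec = spec, in_channels = as.integer(in_channels))
  if (spec$family == "fully_connected") {
    d_in <- in_channels * NPOS
    model$fc <- list(
      W1 = glorot_uniform(d_in, spec$hidden, c(d_in, spec$hidden)),
      b1 = numeric(spec$hidden),
      W2 = glorot_uniform(spec$hidden, NPOS, c(spec$hidden, NPOS)),
      b2 = numeric(NPOS))
    class(model) <- "hvf_net"
    return(model)
  }
  blocks <- vector("list", spec$k)
  pool_channels <- in_channels  # cascade: running concat width
  cur <- in_channels
  for (bi in seq_len(spec$k)) {
    cin <- if (spec$family == "cascade") pool_channels else cur
    widths <- spec$filters
    units <- list(new_unit(cin, widths[1], spec$batch_norm),
                  new_unit(widths[1], widths[2], spec$batch_norm),
                  new_unit(widths[2], widths[3], spec$batch_norm))
    blk <- list(units = units, in_channels = cin,
                out_channels = widths[3])
    if (spec$family == "residual" && cin != widths[3]) {
      blk$proj <- new_conv1(cin, widths[3])
    }
    blocks[[bi]] <- blk
    pool_channels <- pool_channels + widths[3]
    cur <- widths[3]
  }
  model$blocks <- blocks
  head_in <- if (spec$family == "cascade") pool_channels else cur
  model$head <- new_conv1(head_in, 1L)
  class(model) <- "hvf_net"
  model
}

#' @export
print.hvf_net <- function(x, ...) {
  cat(sprintf("<hvf_net: %s, %d input channel(s), %s parameters>\n",
              x$spec$family, x$in_channels,
              format(model_n_params(x), big.mark = ",")))
  invisible(x)
}

#' @param model An `hvf_net`.
#' @rdname build_model
#' @export
model_n_params <- function(model) {
  sum(vapply(collect_params(model), length, integer(1)))
}

#' Masked pointwise mean absolute error
#'
#' The training and evaluation loss: the mean of |predicted - target| over
#' the 54 valid cells only. Invalid cells contribute nothing to the value
#' (nor, during training, to the gradient), so their content is arbitrary.
#'
#' @param predicted,target 8 x 9 numeric matrices.
#' @param mask 8 x 9 logical validity mask (e.g. [hvf_mask()]).
#' @return The masked PMAE in dB.
#' @export
masked_pmae_loss <- function(predicted, target, mask) {
  stopifnot(identical(dim(predicted), dim(target)),
            identical(dim(predicted), dim(mask)))
  if (!any(mask)) abort("mask is empty.")
  mean(abs(predicted[mask] - target[mask]))
}

#' Training configuration
#'
#' Optimisation settings for [train_model()]. The `full` profile matches
#' the full-scale protocol (1000 epochs, Adam at 1e-3); the `desk` profile
#' is sized for a single CPU (50 epochs, Adam at 1e-2 — the higher rate
#' compensates for the vastly smaller number of optimisation steps).
#' Batch size is 32 and initialisation is Xavier in both profiles.
#'
#' @param profile `"desk"` or `"full"`.
#' @param epochs,batch_size,lr Override the profile defaults.
#' @param validation_bin Bin centre (years) whose pairs drive model
#'   selection validation.
#' @param seed Integer seed controlling initialisation and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "full"), epochs = NULL,
                         batch_size = 32L, lr = NULL,
                         validation_bin = 1.0, seed = 1L) {
  profile <- match.arg(profile)
  epochs <- epochs %||% if (profile == "desk") 50L else 1000L
  lr <- lr %||% if (profile == "desk") 1e-2 else 1e-3
  stopifnot(epochs >= 0L, batch_size >= 1L, lr > 0)
  structure(list(profile = profile, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 validation_bin = validation_bin, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an encoded training set from pairs
#'
#' Encodes each pair's input test as an input tensor batch and its target
#' test as a masked 72-cell target row, ready for [train_model()].
#'
#' @param pairs Pair tibble ([make_pairs()]).
#' @param fields Field tibble the pairs refer to.
#' @inheritParams encode_input
#' @return A list with `X` ((n*72) x C input activations), `target`
#'   (n x 72), `mask` (n x 72), `n`, and the pair ids.
#' @export
make_training_set <- function(pairs, fields, covariates = character(),
                              age_div100 = FALSE) {
  pm <- pair_matrices(pairs, fields)
  input_rows <- fields[pm$input_row, , drop = FALSE]
  X <- encode_batch(input_rows, covariates, age_div100)
  n <- nrow(pairs)
  target <- matrix(0, n, NPOS)
  mk <- matrix(0, n, NPOS)
  for (i in seq_len(n)) {
    pos <- map54to72(pm$eye[i])
    target[i, pos] <- pm$target[i, ]
    mk[i, pos] <- 1
  }
  list(X = X, target = target, mask = mk, n = n, pair_id = pairs$pair_id,
       eye = pm$eye, covariates = covariates, age_div100 = age_div100)
}

# Batch loss + gradient wrt predictions (per-sample masked MAE, averaged
# over samples; each sample's valid-cell count is its own denominator).
batch_loss_grad <- function(pred, target, mk) {
  d <- (pred - target) * mk
  per_cell <- rowSums(mk)
  loss <- mean(rowSums(abs(d)) / per_cell)
  grad <- sign(d) * mk / (per_cell * nrow(pred))
  list(loss = loss, grad = grad)
}

# Validation PMAE of a model on an encoded set (eval mode).
eval_pmae <- function(model, set) {
  pred <- net_forward(model, set$X, set$n, training = FALSE)$pred
  d <- (pred - set$target) * set$mask
  mean(rowSums(abs(d)) / rowSums(set$mask))
}

#' Train a network with masked PMAE loss
#'
#' Minibatch Adam on the masked pointwise MAE. Validation PMAE is measured
#' after every epoch and the returned model carries the weights of the
#' best (lowest validation PMAE) epoch, not the last. Training is
#' deterministic under `config$seed`. A non-finite loss aborts with the
#' epoch reported. With `epochs = 0` the model is only evaluated
#' (used for protocol instantiation).
#'
#' @param model An [build_model()] network.
#' @param train_set,val_set Encoded sets from [make_training_set()].
#' @param config A [train_config()].
#' @return A list of class `hvf_fit`: `model` (best-epoch weights),
#'   `history` tibble (`epoch`, `train_loss`, `val_pmae`), `best_epoch`,
#'   `best_val_pmae`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "hvf_net"), inherits(config, "train_config"))
  if (train_set$n == 0L || val_set$n == 0L) {
    abort("empty training or validation set.")
  }
  withr::with_seed(config$seed, {
    params <- collect_params(model)
    state <- adam_init(params)
    best <- list(model = model, val = eval_pmae(model, val_set), epoch = 0L)
    history <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_set$n)
      nb <- ceiling(train_set$n / config$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        sel <- ord[((b - 1L) * config$batch_size + 1L):
                     min(b * config$batch_size, train_set$n)]
        rows <- as.vector(t(outer((sel - 1L) * NPOS, 1:NPOS, "+")))
        model <- assign_params(model, params)
        fwd <- net_forward(model, train_set$X[rows, , drop = FALSE],
                           length(sel), training = TRUE)
        model <- fwd$model  # BN running-stat updates
        lg <- batch_loss_grad(fwd$pred, train_set$target[sel, , drop = FALSE],
                              train_set$mask[sel, , drop = FALSE])
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d.",
                        epoch))
        }
        grads <- net_backward(model, fwd, lg$grad)
        upd <- adam_step(params, grads, state, config$lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(sel)
      }
      model <- assign_params(model, params)
      val <- eval_pmae(model, val_set)
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = ep_loss / train_set$n,
                                 val_pmae = val)
      if (val < best$val) best <- list(model = model, val = val,
                                       epoch = epoch)
    }
    structure(list(model = best$model,
                   history = dplyr::bind_rows(history),
                   best_epoch = best$epoch, best_val_pmae = best$val,
                   config = config),
              class = "hvf_fit")
  })
}

#' @export
print.hvf_fit <- function(x, ...) {
  cat(sprintf("<hvf_fit: best val PMAE %.3f dB at epoch %d/%d>\n",
              x$best_val_pmae, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @param x An `hvf_fit`.
#' @param ... Unused.
#' @rdname train_model
#' @export
tidy.hvf_fit <- function(x, ...) x$history

#' @rdname train_model
#' @export
glance.hvf_fit <- function(x, ...) {
  tibble(best_epoch = x$best_epoch, best_val_pmae = x$best_val_pmae,
         epochs = nrow(x$history))
}

# Pairs of (train, val) encoded sets for one fold of a split plan.
fold_sets <- function(pairs, fields, plan, fold, covariates,
                      age_div100 = FALSE) {
  pp <- add_split(pairs, plan)
  train <- pp %>% filter(.data$part != "test", .data$part != fold)
  val <- pp %>% filter(.data$part == fold)
  list(train = make_training_set(train, fields, covariates, age_div100),
       val = make_training_set(val, fields, covariates, age_div100))
}

#' Cross-validated model-architecture selection
#'
#' Trains each candidate architecture on every cross-validation fold using
#' the pairs of the validation bin (default one year) and records the
#' lowest validation PMAE per architecture and fold. The ranking is
#' deterministic given the configured seed.
#'
#' @param specs Named list of [arch_spec()] candidates.
#' @param pairs,fields Pair and field tibbles.
#' @param plan A [split_patients()] plan.
#' @param config A [train_config()].
#' @param covariates Covariates to encode (see [encode_input()]).
#' @return A tibble (`arch`, `fold`, `best_val_pmae`, `best_epoch`,
#'   `n_params`), one row per architecture x fold.
#' @export
run_model_selection <- function(specs, pairs, fields, plan,
                                config = train_config(),
                                covariates = character()) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    abort("`specs` must be a named list.")
  }
  folds <- sort(unique(plan$part[plan$part != "test"]))
  sel <- pairs %>% filter(.data$bin_center == config$validation_bin)
  out <- list()
  for (nm in names(specs)) {
    for (f in folds) {
      sets <- fold_sets(sel, fields, plan, f, covariates)
      model <- withr::with_seed(
        config$seed + which(folds == f),
        build_model(specs[[nm]], n_input_channels(covariates)))
      fit <- train_model(model, sets$train, sets$val, config)
      out[[length(out) + 1L]] <- tibble(
        arch = nm, fold = f, best_val_pmae = fit$best_val_pmae,
        best_epoch = fit$best_epoch, n_params = model_n_params(model))
    }
  }
  dplyr::bind_rows(out)
}

#' Interval transfer-learning chain
#'
#' Trains one model per (interval bin, fold): the first bin trains from
#' scratch, and every later bin warm-starts from the same fold's model for
#' the immediately preceding bin. With the full protocol (10 bins, 10
#' folds) this produces 100 trained models.
#'
#' @inheritParams run_model_selection
#' @param spec The [arch_spec()] to train.
#' @param bins Bin centres to chain, in increasing order; default all bins
#'   present in `pairs`.
#' @return An object of class `model_bundle`: fitted models indexed by bin
#'   and fold plus a lineage table (`bin_center`, `fold`, `lineage`,
#'   `best_val_pmae`, `best_epoch`).
#' @export
transfer_train_chain <- function(pairs, fields, plan, spec,
                                 config = train_config(),
                                 covariates = character(), bins = NULL) {
  folds <- sort(unique(plan$part[plan$part != "test"]))
  bins <- bins %||% sort(unique(pairs$bin_center))
  if (is.unsorted(bins, strictly = TRUE)) {
    abort("`bins` must be strictly increasing.")
  }
  models <- list()
  rows <- list()
  for (f in folds) {
    prev <- NULL
    for (b in bins) {
      bp <- pairs %>% filter(.data$bin_center == b)
      if (nrow(bp) == 0L) abort(sprintf("no pairs in bin %.1f.", b))
      sets <- fold_sets(bp, fields, plan, f, covariates)
      model <- if (is.null(prev)) {
        withr::with_seed(config$seed + which(folds == f),
                         build_model(spec, n_input_channels(covariates)))
      } else {
        prev  # warm start: weights carried from the preceding interval
      }
      fit <- train_model(model, sets$train, sets$val, config)
      prev <- fit$model
      models[[as.character(b)]][[f]] <- fit$model
      rows[[length(rows) + 1L]] <- tibble(
        bin_center = b, fold = f,
        lineage = if (b == bins[1L]) NA_real_ else bins[match(b, bins) - 1L],
        best_val_pmae = fit$best_val_pmae, best_epoch = fit$best_epoch)
    }
  }
  structure(list(models = models, table = dplyr::bind_rows(rows),
                 spec = spec, covariates = covariates, config = config,
                 folds = folds, bins = bins),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle: %d bins x %d folds = %d models (%s)>\n",
              length(x$bins), length(x$folds),
              nrow(x$table), x$spec$family))
  invisible(x)
}

#' @param x A `model_bundle`.
#' @param ... Unused.
#' @rdname transfer_train_chain
#' @export
tidy.model_bundle <- function(x, ...) x$table

#' Fold-ensemble prediction
#'
#' For each pair, runs the input field through all fold models of the
#' pair's interval bin, averages the predictions cell-wise and clamps to
#' \[0, 50\] dB — the evaluation-time ensemble over the cross-validation
#' folds.
#'
#' @param bundle A [transfer_train_chain()] bundle.
#' @param pairs,fields Pair and field tibbles; every pair's bin must be
#'   present in the bundle with all folds trained.
#' @return A tibble: `pair_id` plus predicted `s01`...`s54`.
#' @export
predict_ensemble <- function(bundle, pairs, fields) {
  stopifnot(inherits(bundle, "model_bundle"))
  missing_bins <- setdiff(unique(pairs$bin_center), bundle$bins)
  if (length(missing_bins) > 0L) {
    abort(sprintf("bundle has no models for bin(s) %s.",
                  paste(missing_bins, collapse = ", ")))
  }
  pm <- pair_matrices(pairs, fields)
  pred54 <- matrix(NA_real_, nrow(pairs), 54L)
  for (b in unique(pairs$bin_center)) {
    sel <- which(pairs$bin_center == b)
    fold_models <- bundle$models[[as.character(b)]]
    if (length(fold_models) < length(bundle$folds) ||
        any(!bundle$folds %in% names(fold_models))) {
      abort(sprintf("bin %.1f is missing fold models.", b))
    }
    X <- encode_batch(fields[pm$input_row[sel], , drop = FALSE],
                      bundle$covariates)
    acc <- matrix(0, length(sel), NPOS)
    for (f in bundle$folds) {
      acc <- acc + net_forward(fold_models[[f]], X, length(sel),
                               training = FALSE)$pred
    }
    acc <- acc / length(bundle$folds)
    for (i in seq_along(sel)) {
      pred54[sel[i], ] <- acc[i, map54to72(pm$eye[sel[i]])]
    }
  }
  pred54 <- pmin(pmax(pred54, 0), 50)
  colnames(pred54) <- s_cols()
  dplyr::bind_cols(tibble(pair_id = pairs$pair_id), as_tibble(pred54))
}

#' All covariate combinations
#'
#' Enumerates the 16 subsets of the four candidate covariates, with the
#' input channel count each one implies.
#'
#' @return A tibble with list-column `covariates` and `in_channels`.
#' @export
covariate_combinations <- function() {
  subsets <- unlist(lapply(0:4, function(m)
    utils::combn(COVARIATE_ORDER, m, simplify = FALSE)), recursive = FALSE)
  tibble(
    covariates = subsets,
    label = vapply(subsets, function(s)
      if (length(s) == 0L) "(none)" else paste(s, collapse = "+"),
      character(1)),
    in_channels = vapply(subsets, n_input_channels, integer(1))
  )
}
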