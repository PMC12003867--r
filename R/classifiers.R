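#' Fixed tissue / concentration embedding table
#'
#' One length-60 vector per tissue and per concentration, drawn once from a
#' seeded normal (sd 0.1) and never updated by training; the vectors are
#' added to the input across the channel axis at every time step, which is
#' the only addition compatible with a 2000 x 60 input without further
#' assumptions.
#'
#' @param seed integer seed.
#' @param n_channels number of channels (60).
#' @param sd scale of the embedding entries.
#' @return an `sw_embedding` with `tissue_vectors` (4 x 60) and
#'   `concentration_vectors` (3 x 60), `frozen = TRUE`.
#' @export
make_embedding_table <- function(seed = 1L, n_channels = 60L, sd = 0.1) {
  with_seed(derive_seed(seed, "embeddings"), {
    structure(list(
      tissue_vectors = matrix(rnorm(length(TISSUES) * n_channels, sd = sd),
                              nrow = length(TISSUES),
                              dimnames = list(names(TISSUES), NULL)),
      concentration_vectors = matrix(
        rnorm(length(CONCENTRATIONS) * n_channels, sd = sd),
        nrow = length(CONCENTRATIONS),
        dimnames = list(names(CONCENTRATIONS), NULL)),
      frozen = TRUE, seed = seed
    ), class = "sw_embedding")
  })
}

#' Add covariate embeddings to a model input
#'
#' Returns `x + tissue_vector(t) + concentration_vector(c)`, the two
#' length-60 vectors broadcast over every time step. Pure function; unknown
#' codes are rejected.
#'
#' @param x matrix time x channels.
#' @param tissue integer tissue code (1-4).
#' @param conc integer concentration code (1-3).
#' @param table an `sw_embedding`.
#' @return matrix of the same dimension.
#' @export
embed_covariates <- function(x, tissue, conc, table) {
  if (!tissue %in% TISSUES) stop(sprintf("unknown tissue code %s", tissue))
  if (!conc %in% CONCENTRATIONS) {
    stop(sprintf("unknown concentration code %s", conc))
  }
  v <- table$tissue_vectors[tissue, ] + table$concentration_vectors[conc, ]
  sweep(x, 2, v, "+")
}

#' Training specification for one classifier
#'
#' Mirrors the training protocol: mini-batch gradient descent with the Adam
#' optimiser, batch size 30, and a configurable epoch budget (200 at full
#' scale; the desk-scale default is 20). `subsample` thins the 2000-step
#' time axis by the given factor before the network (ci profile uses 4).
#'
#' @param arch "ict", "fcn" or "cnn".
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param n_filters filters per branch (scaled-down default; the reference
#'   designs use 32 per inception branch / 128 in the first FCN block).
#' @param depth inception modules for the ict architecture (6 at full
#'   scale, 3 in the ci profile).
#' @param kernels inception kernel sizes. The reference design uses
#'   40/20/10 on the full 2000-step axis; the default here is scaled by the
#'   default `subsample` so the temporal receptive field in seconds is
#'   unchanged.
#' @param subsample temporal subsampling factor applied to inputs.
#' @param seed integer seed for weight init and batch order.
#' @param label_mode "correct" or "shuffled" (bookkeeping tag; shuffling
#'   itself is done by [shuffle_labels()]).
#' @return an `sw_train_spec`.
#' @export
train_spec <- function(arch = c("ict", "fcn", "cnn"), epochs = 20L,
                       batch_size = 30L, lr = 1e-3, n_filters = 4L,
                       depth = 3L, kernels = c(10L, 5L, 3L),
                       subsample = 4L, seed = 1L,
                       label_mode = c("correct", "shuffled")) {
  arch <- match.arg(arch)
  label_mode <- match.arg(label_mode)
  stopifnot(batch_size >= 1, epochs >= 1)
  structure(list(arch = arch, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 n_filters = as.integer(n_filters), depth = as.integer(depth),
                 kernels = as.integer(kernels),
                 subsample = as.integer(subsample), seed = as.integer(seed),
                 label_mode = label_mode),
            class = "sw_train_spec")
}

# Prepare one interference matrix for the network: embed covariates, thin
# the time axis, and replace residual NaN with 0 (normalized units).
prep_input <- function(x, tissue, conc, embedding, subsample) {
  x <- embed_covariates(x, tissue, conc, embedding)
  if (subsample > 1) {
    x <- x[seq(1, nrow(x), by = subsample), , drop = FALSE]
  }
  x[is.na(x)] <- 0
  x
}

#' Train one time-series classifier
#'
#' Trains the requested architecture on embedded interference matrices with
#' softmax cross-entropy, mini-batches and Adam. Inputs are a list of
#' 2000 x 60 matrices with per-dataset tissue/concentration codes; the
#' embedding table is frozen (stored, never updated). Deterministic given
#' the spec seed.
#'
#' @param x_list named list of interference matrices (time x channel).
#' @param labels integer 0/1 vector aligned to `x_list`.
#' @param tissues,concs integer covariate codes aligned to `x_list`.
#' @param embedding an `sw_embedding`.
#' @param spec an `sw_train_spec`.
#' @return an `sw_classifier` with the trained parameters, the embedding,
#'   the spec and the per-epoch training-loss history.
#' @export
train_classifier <- function(x_list, labels, tissues, concs, embedding,
                             spec = train_spec()) {
  n <- length(x_list)
  stopifnot(n > 0, length(labels) == n, length(tissues) == n,
            length(concs) == n)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("class-degenerate training set: both classes required")
  }
  inputs <- lapply(seq_len(n), function(i) {
    prep_input(x_list[[i]], tissues[i], concs[i], embedding, spec$subsample)
  })
  T <- nrow(inputs[[1]]); C <- ncol(inputs[[1]])
  Xall <- do.call(rbind, inputs)
  history <- numeric(spec$epochs)
  with_seed(derive_seed(spec$seed, "train", spec$arch), {
    params <- net_init(spec$arch, C, spec$n_filters, spec$depth,
                       spec$kernels)
    state <- adam_init(params)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        B <- length(idx)
        rows <- rep((idx - 1L) * T, each = T) + seq_len(T)
        out <- net_fwbw(spec$arch, params, Xall[rows, , drop = FALSE],
                        B, T, labels[idx])
        if (!is.finite(out$loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d; aborting training", ep))
        }
        upd <- adam_step(params, out$grads, state, lr = spec$lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + out$loss; nb <- nb + 1
      }
      history[ep] <- ep_loss / nb
    }
    structure(list(arch = spec$arch, params = params, embedding = embedding,
                   spec = spec, loss_history = history,
                   input_dim = c(T, C)),
              class = "sw_classifier")
  })
}

#' Class-probability predictions
#'
#' One two-component probability row per input matrix (softmax output, rows
#' sum to 1). Batching does not change the result.
#'
#' @param model an `sw_classifier`.
#' @param x_list list of interference matrices.
#' @param tissues,concs covariate codes aligned to `x_list`.
#' @param batch_size prediction batch size.
#' @return data.frame with `dataset_id` (names of `x_list`), `p0`, `p1`.
#' @export
predict_proba <- function(model, x_list, tissues, concs, batch_size = 64L) {
  n <- length(x_list)
  spec <- model$spec
  inputs <- lapply(seq_len(n), function(i) {
    x <- prep_input(x_list[[i]], tissues[i], concs[i], model$embedding,
                    spec$subsample)
    if (!all(dim(x) == model$input_dim)) {
      stop("input dimensions do not match the trained model")
    }
    x
  })
  T <- model$input_dim[1]
  P <- matrix(NA_real_, n, 2)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    X <- do.call(rbind, inputs[idx])
    P[idx, ] <- net_fwbw(spec$arch, model$params, X, length(idx), T)$probs
  }
  data.frame(dataset_id = names(x_list) %||% as.character(seq_len(n)),
             p0 = P[, 1], p1 = P[, 2], stringsAsFactors = FALSE)
}
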