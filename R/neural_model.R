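# Hybrid embedding -> biLSTM -> Transformer-encoder -> regressor models
# for fragment-ion intensity and iRT prediction, with masked losses,
# dataset splitting, Adam training with step-decayed learning rate, and
# best-on-validation checkpoint selection.

#' Ion (fragment-intensity) model configuration
#'
#' Defaults follow the full-scale architecture: 192-dim amino-acid and
#' 64-dim charge embeddings, two bidirectional LSTM layers of hidden
#' size 512, eight Transformer encoder layers with eight attention
#' heads, and a per-position linear projection to the 8 ion channels.
#' The bidirectional LSTM output (2 x hidden) is linearly projected to
#' `d_model` before sinusoidal position encoding and the encoder stack.
#'
#' @param aa_embed_dim,charge_embed_dim Embedding widths.
#' @param lstm_hidden,lstm_layers biLSTM hidden size per direction and depth.
#' @param d_model Transformer width (divisible by `attention_heads`).
#' @param encoder_layers,attention_heads Encoder stack shape.
#' @param ffn_dim Feed-forward inner width.
#' @param max_len Maximum peptide length L the model accepts.
#' @param allowed_charges Precursor charges the charge embedding covers.
#' @return A config list of class `ion_model_config`.
#' @export
ion_model_config <- function(aa_embed_dim = 192L, charge_embed_dim = 64L,
                             lstm_hidden = 512L, lstm_layers = 2L,
                             d_model = 512L, encoder_layers = 8L,
                             attention_heads = 8L, ffn_dim = 2L * d_model,
                             max_len = 50L, allowed_charges = 1:6) {
  stopifnot(d_model %% attention_heads == 0L, aa_embed_dim > 0,
            charge_embed_dim > 0, lstm_hidden > 0, lstm_layers >= 1L,
            encoder_layers >= 1L)
  structure(list(task = "ion", aa_embed_dim = as.integer(aa_embed_dim),
                 charge_embed_dim = as.integer(charge_embed_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 d_model = as.integer(d_model),
                 encoder_layers = as.integer(encoder_layers),
                 attention_heads = as.integer(attention_heads),
                 ffn_dim = as.integer(ffn_dim), max_len = as.integer(max_len),
                 allowed_charges = as.integer(allowed_charges),
                 output_dim = 8L),
            class = "ion_model_config")
}

#' Reduced ion model for CPU-scale experiments
#'
#' A small variant of [ion_model_config()] (32/16-dim embeddings, hidden
#' 64, one biLSTM layer, two encoder layers with two heads) used in
#' overfitting sanity checks and examples.
#' @param max_len Maximum peptide length.
#' @return An `ion_model_config`.
#' @export
reduced_ion_config <- function(max_len = 20L) {
  ion_model_config(aa_embed_dim = 32L, charge_embed_dim = 16L,
                   lstm_hidden = 64L, lstm_layers = 1L, d_model = 32L,
                   encoder_layers = 2L, attention_heads = 2L, ffn_dim = 64L,
                   max_len = max_len)
}

#' RT (iRT) model configuration
#'
#' The retention-time regressor: 256-dim amino-acid embedding, biLSTM,
#' and an ensemble of encoder stacks of depths `ensemble_depths`
#' (default 4 to 8). Each member pools per-position features through a
#' learned softmax-normalized position weight and maps the pooled vector
#' to one scalar; the ensemble prediction is the mean over members.
#'
#' @inheritParams ion_model_config
#' @param ensemble_depths Encoder depths of the ensemble members.
#' @return A config list of class `rt_model_config`.
#' @export
rt_model_config <- function(aa_embed_dim = 256L, lstm_hidden = 512L,
                            lstm_layers = 2L, d_model = 512L,
                            ensemble_depths = 4:8, attention_heads = 8L,
                            ffn_dim = 2L * d_model, max_len = 50L) {
  stopifnot(length(ensemble_depths) >= 1L, all(ensemble_depths >= 1L),
            all(ensemble_depths <= 12L), d_model %% attention_heads == 0L)
  structure(list(task = "rt", aa_embed_dim = as.integer(aa_embed_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 d_model = as.integer(d_model),
                 ensemble_depths = as.integer(ensemble_depths),
                 attention_heads = as.integer(attention_heads),
                 ffn_dim = as.integer(ffn_dim), max_len = as.integer(max_len)),
            class = "rt_model_config")
}

#' Reduced RT ensemble for CPU-scale experiments
#' @param max_len Maximum peptide length.
#' @param ensemble_depths Encoder depths (default 1 and 2).
#' @return An `rt_model_config`.
#' @export
reduced_rt_config <- function(max_len = 20L, ensemble_depths = c(1L, 2L)) {
  rt_model_config(aa_embed_dim = 32L, lstm_hidden = 48L, lstm_layers = 1L,
                  d_model = 32L, ensemble_depths = ensemble_depths,
                  attention_heads = 2L, ffn_dim = 64L, max_len = max_len)
}

#' Retention-time normalization scale
#'
#' Training targets are normalized as `z = (RT - rt_min) / (rt_max -
#' rt_min)`; predictions are mapped back. The defaults (-100, 200) are
#' a fixed wide window in iRT units so one scale serves all datasets.
#'
#' @param rt_min,rt_max Scale anchors in RT/iRT units.
#' @return List with `rt_min`, `rt_max`.
#' @export
rt_scale <- function(rt_min = -100, rt_max = 200) {
  stopifnot(rt_max > rt_min)
  list(rt_min = rt_min, rt_max = rt_max)
}

#' Training configuration
#'
#' Adam optimization of the masked MSE (ion) or RMSE (RT) loss, with the
#' learning rate multiplied by `lr_decay_factor` at each milestone epoch
#' (defaults: 2/3 and 5/6 of `max_epochs`). The checkpoint returned is
#' the one with the best validation metric, not the last epoch.
#'
#' @param max_epochs Number of epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate (1e-3 is used for a
#'   first large pretraining corpus, 1e-4 otherwise).
#' @param lr_decay_factor Multiplicative decay at each milestone.
#' @param decay_milestones Epochs at which to decay; `NULL` for defaults.
#' @param seed Seed controlling init-independent training randomness
#'   (shuffling).
#' @param eval_every Validation cadence in epochs.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-4, lr_decay_factor = 0.1,
                         decay_milestones = NULL, seed = 1L,
                         eval_every = 10L) {
  stopifnot(learning_rate > 0, max_epochs >= 1L)
  if (is.null(decay_milestones))
    decay_milestones <- unique(c(ceiling(2 / 3 * max_epochs),
                                 ceiling(5 / 6 * max_epochs)))
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 decay_milestones = as.integer(decay_milestones),
                 seed = as.integer(seed), eval_every = as.integer(eval_every)),
            class = "train_config")
}

# ---- weight initialization ----------------------------------------------

unif_mat <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

init_lstm <- function(w, prefix, in_dim, H) {
  for (dir in c("f", "b")) {
    w[[paste0(prefix, dir, "_Wx")]] <- unif_mat(in_dim, 4L * H, in_dim)
    w[[paste0(prefix, dir, "_Wh")]] <- unif_mat(H, 4L * H, H)
    bias <- stats::runif(4L * H, -1 / sqrt(H), 1 / sqrt(H))
    bias[(H + 1L):(2L * H)] <- bias[(H + 1L):(2L * H)] + 1  # forget gate
    w[[paste0(prefix, dir, "_b")]] <- bias
  }
  w
}

init_encoder <- function(w, prefix, d, ffn) {
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    w[[paste0(prefix, nm)]] <- unif_mat(d, d, d)
  for (nm in c("bq", "bk", "bv", "bo"))
    w[[paste0(prefix, nm)]] <- numeric(d)
  w[[paste0(prefix, "ln1_g")]] <- rep(1, d)
  w[[paste0(prefix, "ln1_b")]] <- numeric(d)
  w[[paste0(prefix, "W1")]] <- unif_mat(d, ffn, d)
  w[[paste0(prefix, "b1")]] <- numeric(ffn)
  w[[paste0(prefix, "W2")]] <- unif_mat(ffn, d, ffn)
  w[[paste0(prefix, "b2")]] <- numeric(d)
  w[[paste0(prefix, "ln2_g")]] <- rep(1, d)
  w[[paste0(prefix, "ln2_b")]] <- numeric(d)
  w
}

init_trunk <- function(cfg, with_charge) {
  V <- length(token_vocab())
  w <- list()
  w$E_aa <- matrix(stats::rnorm(V * cfg$aa_embed_dim, 0, 0.1),
                   V, cfg$aa_embed_dim)
  in_dim <- cfg$aa_embed_dim
  if (with_charge) {
    w$E_ch <- matrix(stats::rnorm(6L * cfg$charge_embed_dim, 0, 0.1),
                     6L, cfg$charge_embed_dim)
    in_dim <- in_dim + cfg$charge_embed_dim
  }
  H <- cfg$lstm_hidden
  for (l in seq_len(cfg$lstm_layers)) {
    w <- init_lstm(w, paste0("lstm", l, "_"), in_dim, H)
    in_dim <- 2L * H
  }
  w$proj_W <- unif_mat(2L * H, cfg$d_model, 2L * H)
  w$proj_b <- numeric(cfg$d_model)
  w
}

#' Build (initialize) an ion model
#'
#' @param cfg An [ion_model_config()].
#' @param seed Seed for weight initialization.
#' @return Model handle: list with `cfg`, `weights`, `task`, `provenance`.
#' @export
build_ion_model <- function(cfg = ion_model_config(), seed = 1L) {
  set.seed(seed)
  w <- init_trunk(cfg, with_charge = TRUE)
  for (k in seq_len(cfg$encoder_layers))
    w <- init_encoder(w, paste0("enc", k, "_"), cfg$d_model, cfg$ffn_dim)
  w$out_W <- unif_mat(cfg$d_model, cfg$output_dim, cfg$d_model)
  w$out_b <- numeric(cfg$output_dim)
  structure(list(cfg = cfg, weights = w, task = "ion",
                 provenance = "initialized", val_metric = NA_real_),
            class = "phospho_ion_model")
}

#' Build (initialize) an RT ensemble
#'
#' @param cfg An [rt_model_config()].
#' @param seed Seed for weight initialization.
#' @param scale An [rt_scale()].
#' @return Ensemble handle: list with `cfg`, `members`, `scale`.
#' @export
build_rt_ensemble <- function(cfg = rt_model_config(), seed = 1L,
                              scale = rt_scale()) {
  if (!length(cfg$ensemble_depths)) stop("empty ensemble")
  members <- vector("list", length(cfg$ensemble_depths))
  for (i in seq_along(cfg$ensemble_depths)) {
    set.seed(seed + i - 1L)
    w <- init_trunk(cfg, with_charge = FALSE)
    for (k in seq_len(cfg$ensemble_depths[i]))
      w <- init_encoder(w, paste0("enc", k, "_"), cfg$d_model, cfg$ffn_dim)
    w$pool_W <- unif_mat(cfg$d_model, 1L, cfg$d_model)
    w$pool_b <- numeric(1L)
    w$head_W <- unif_mat(cfg$d_model, 1L, cfg$d_model)
    w$head_b <- numeric(1L)
    members[[i]] <- list(depth = cfg$ensemble_depths[i], weights = w)
  }
  structure(list(cfg = cfg, members = members, scale = scale, task = "rt",
                 provenance = "initialized", val_metric = NA_real_),
            class = "phospho_rt_ensemble")
}

# ---- batch preparation ---------------------------------------------------

pad_id <- function() unname(token_vocab()[["<pad>"]])

# token matrix B x S (S = max_len + 1: marker + residues, padded)
tokens_matrix <- function(peptides, max_len) {
  S <- max_len + 1L
  B <- length(peptides)
  tm <- matrix(pad_id(), B, S)
  for (b in seq_len(B)) {
    ids <- encode_rt_input(peptides[[b]])
    if (length(ids) > S)
      stop("peptide longer than model max_len = ", max_len)
    tm[b, seq_along(ids)] <- ids
  }
  tm
}

sinusoidal_pe <- function(S, d) {
  pe <- matrix(0, S, d)
  pos <- seq_len(S) - 1L
  for (i in seq_len(ceiling(d / 2))) {
    div <- 10000^(2 * (i - 1) / d)
    pe[, 2L * i - 1L] <- sin(pos / div)
    if (2L * i <= d) pe[, 2L * i] <- cos(pos / div)
  }
  pe
}

# ---- forward passes ------------------------------------------------------

bilstm_dir <- function(tape, wn, prefix, x, B, S, H, reverse) {
  h <- ad_leaf(tape, matrix(0, B, H))
  cc <- ad_leaf(tape, matrix(0, B, H))
  Wx <- wn[[paste0(prefix, "_Wx")]]
  Wh <- wn[[paste0(prefix, "_Wh")]]
  bb <- wn[[paste0(prefix, "_b")]]
  outs <- vector("list", S)
  for (t in if (reverse) seq.int(S, 1L) else seq_len(S)) {
    xt <- ad_rows(tape, x, (seq_len(B) - 1L) * S + t)
    z <- ad_bias(tape, ad_add(tape, ad_matmul(tape, xt, Wx),
                              ad_matmul(tape, h, Wh)), bb)
    gi <- ad_sigmoid(tape, ad_cols(tape, z, seq_len(H)))
    gf <- ad_sigmoid(tape, ad_cols(tape, z, H + seq_len(H)))
    gg <- ad_tanh(tape, ad_cols(tape, z, 2L * H + seq_len(H)))
    go <- ad_sigmoid(tape, ad_cols(tape, z, 3L * H + seq_len(H)))
    cc <- ad_add(tape, ad_mul(tape, gf, cc), ad_mul(tape, gi, gg))
    h <- ad_mul(tape, go, ad_tanh(tape, cc))
    outs[[t]] <- h
  }
  outs
}

bilstm_layer <- function(tape, wn, layer, x, B, S, H) {
  fw <- bilstm_dir(tape, wn, paste0("lstm", layer, "_f"), x, B, S, H, FALSE)
  bw <- bilstm_dir(tape, wn, paste0("lstm", layer, "_b"), x, B, S, H, TRUE)
  parts <- vector("list", S)
  idxs <- vector("list", S)
  for (t in seq_len(S)) {
    parts[[t]] <- ad_concat_cols(tape, list(fw[[t]], bw[[t]]))
    idxs[[t]] <- (seq_len(B) - 1L) * S + t
  }
  ad_stack_rows_at(tape, parts, idxs, B * S)
}

encoder_layer <- function(tape, wn, prefix, x, B, S, heads, keymask) {
  d <- ncol(x$val)
  dk <- d %/% heads
  q <- ad_bias(tape, ad_matmul(tape, x, wn[[paste0(prefix, "Wq")]]),
               wn[[paste0(prefix, "bq")]])
  k <- ad_bias(tape, ad_matmul(tape, x, wn[[paste0(prefix, "Wk")]]),
               wn[[paste0(prefix, "bk")]])
  v <- ad_bias(tape, ad_matmul(tape, x, wn[[paste0(prefix, "Wv")]]),
               wn[[paste0(prefix, "bv")]])
  parts <- vector("list", B)
  idxs <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    qb <- ad_rows(tape, q, rows)
    kb <- ad_rows(tape, k, rows)
    vb <- ad_rows(tape, v, rows)
    maskmat <- matrix(rep(ifelse(keymask[b, ], -1e9, 0), each = S), S, S)
    hparts <- vector("list", heads)
    for (hh in seq_len(heads)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      qh <- ad_cols(tape, qb, cols)
      kh <- ad_cols(tape, kb, cols)
      vh <- ad_cols(tape, vb, cols)
      sc <- ad_scale(tape, ad_matmul_bt(tape, qh, kh), 1 / sqrt(dk))
      sc <- ad_addc(tape, sc, maskmat)
      at <- ad_softmax_rows(tape, sc)
      hparts[[hh]] <- ad_matmul(tape, at, vh)
    }
    parts[[b]] <- ad_concat_cols(tape, hparts)
    idxs[[b]] <- rows
  }
  att <- ad_stack_rows_at(tape, parts, idxs, B * S)
  att <- ad_bias(tape, ad_matmul(tape, att, wn[[paste0(prefix, "Wo")]]),
                 wn[[paste0(prefix, "bo")]])
  x <- ad_layernorm(tape, ad_add(tape, x, att),
                    wn[[paste0(prefix, "ln1_g")]], wn[[paste0(prefix, "ln1_b")]])
  ff <- ad_bias(tape, ad_matmul(
    tape, ad_relu(tape, ad_bias(tape, ad_matmul(tape, x, wn[[paste0(prefix, "W1")]]),
                                wn[[paste0(prefix, "b1")]])),
    wn[[paste0(prefix, "W2")]]), wn[[paste0(prefix, "b2")]])
  ad_layernorm(tape, ad_add(tape, x, ff),
               wn[[paste0(prefix, "ln2_g")]], wn[[paste0(prefix, "ln2_b")]])
}

trunk_forward <- function(tape, wn, cfg, tokens, charges = NULL,
                          n_encoders) {
  B <- nrow(tokens)
  S <- ncol(tokens)
  flat <- as.vector(t(tokens))          # batch-major rows
  x <- ad_rows(tape, wn$E_aa, flat)
  if (!is.null(charges)) {
    ce <- ad_rows(tape, wn$E_ch, as.integer(charges))
    ce <- ad_rows(tape, ce, rep(seq_len(B), each = S))
    x <- ad_concat_cols(tape, list(x, ce))
  }
  H <- cfg$lstm_hidden
  for (l in seq_len(cfg$lstm_layers))
    x <- bilstm_layer(tape, wn, l, x, B, S, H)
  x <- ad_bias(tape, ad_matmul(tape, x, wn$proj_W), wn$proj_b)
  pe <- sinusoidal_pe(S, cfg$d_model)
  x <- ad_addc(tape, x, pe[rep(seq_len(S), times = B), , drop = FALSE])
  keymask <- tokens == pad_id()
  for (k in seq_len(n_encoders))
    x <- encoder_layer(tape, wn, paste0("enc", k, "_"), x, B, S,
                       cfg$attention_heads, keymask)
  x
}

ion_forward <- function(tape, wn, cfg, tokens, charges) {
  x <- trunk_forward(tape, wn, cfg, tokens, charges, cfg$encoder_layers)
  ad_bias(tape, ad_matmul(tape, x, wn$out_W), wn$out_b)
}

rt_member_forward <- function(tape, wn, cfg, depth, tokens) {
  B <- nrow(tokens)
  S <- ncol(tokens)
  x <- trunk_forward(tape, wn, cfg, tokens, NULL, depth)
  w <- ad_bias(tape, ad_matmul(tape, x, wn$pool_W), wn$pool_b)
  w <- ad_reshape_rows(tape, w, B, S)
  w <- ad_addc(tape, w, ifelse(tokens == pad_id(), -1e9, 0))
  w <- ad_softmax_rows(tape, w)
  pooled <- ad_attnpool(tape, w, x, B, S)
  ad_bias(tape, ad_matmul(tape, pooled, wn$head_W), wn$head_b)
}

# ---- losses (plain, exported) -------------------------------------------

#' Masked mean squared error over fragment matrices
#'
#' Mean of squared prediction errors over the cells valid in the target
#' mask only (-1 sentinel cells are excluded and carry no gradient
#' during training).
#'
#' @param pred,target Fragment matrices or aligned lists of matrices.
#' @return Scalar loss.
#' @export
masked_mse <- function(pred, target) {
  if (is.list(pred)) {
    pv <- unlist(lapply(pred, as.vector))
    tv <- unlist(lapply(target, as.vector))
  } else {
    pv <- as.vector(pred); tv <- as.vector(target)
  }
  valid <- tv != -1
  if (!any(valid)) stop("no valid cells")
  mean((pv[valid] - tv[valid])^2)
}

#' Root mean squared error for RT regression
#'
#' @param pred,target Numeric vectors (normalized RT).
#' @return `sqrt(mean((pred - target)^2))`.
#' @export
rt_loss <- function(pred, target) {
  if (!length(pred)) stop("empty batch")
  sqrt(mean((pred - target)^2))
}

# ---- dataset splitting ---------------------------------------------------

#' Split a dataset by modified sequence
#'
#' Partitions entries into train/validation/test so that all charge
#' states of one modified peptide land in the same split (no
#' charge-state leakage).
#'
#' @param sequences Character vector of modified sequences (the grouping
#'   key), one per entry.
#' @param ratios Split ratios summing to 1 (e.g. `c(0.8, 0.1, 0.1)`).
#' @param seed Seed for the shuffle.
#' @return List of integer index vectors, one per ratio, named
#'   `train`/`val`/`test` when 3 ratios are given.
#' @export
split_dataset <- function(sequences, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  groups <- unique(sequences)
  if (length(groups) < length(ratios))
    stop("fewer peptide groups (", length(groups), ") than splits")
  set.seed(seed)
  groups <- sample(groups)
  ng <- length(groups)
  bounds <- round(cumsum(ratios) * ng)
  bounds[length(bounds)] <- ng
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  out <- vector("list", length(ratios))
  for (k in seq_along(ratios)) {
    gk <- groups[starts[k]:bounds[k]]
    out[[k]] <- which(sequences %in% gk)
  }
  if (length(ratios) == 3L) names(out) <- c("train", "val", "test")
  if (length(ratios) == 2L) names(out) <- c("train", "val")
  out
}

# ---- training ------------------------------------------------------------

prepare_ion_batch <- function(peptides, targets, max_len) {
  B <- length(peptides)
  S <- max_len + 1L
  tv <- matrix(0, B * S, 8L)
  mk <- matrix(0, B * S, 8L)
  for (b in seq_len(B)) {
    tg <- targets[[b]]
    if (nrow(tg) > max_len) stop("target matrix taller than max_len")
    rows <- (b - 1L) * S + 1L + seq_len(nrow(tg))
    valid <- tg != -1
    tgz <- tg; tgz[!valid] <- 0
    tv[rows, ] <- tgz
    mk[rows, ] <- valid
  }
  list(target = tv, mask = mk)
}

postprocess_ion <- function(raw, peptides, max_len) {
  S <- max_len + 1L
  out <- vector("list", length(peptides))
  for (b in seq_along(peptides)) {
    m <- raw[((b - 1L) * S + 2L):(b * S), , drop = FALSE]
    m <- pmin(pmax(m, 0), 1)
    msk <- validity_mask(peptides[[b]], max_len)
    m[!msk] <- -1
    mx <- suppressWarnings(max(m[msk]))
    if (is.finite(mx) && mx > 0) m[msk] <- m[msk] / mx
    dimnames(m) <- dimnames(msk)
    out[[b]] <- m
  }
  out
}

current_lr <- function(cfg, epoch) {
  cfg$learning_rate * cfg$lr_decay_factor^sum(epoch > cfg$decay_milestones)
}

#' Train (or fine-tune) the ion model
#'
#' Adam on the masked MSE; the learning rate decays by
#' `lr_decay_factor` at the milestone epochs. Every `eval_every` epochs
#' the model is evaluated on the validation set (median PCC) and the
#' best-scoring weights are kept; passing an already trained model as
#' `model` fine-tunes from its weights (transfer learning) without ever
#' touching the data it was pretrained on.
#'
#' @param model A `phospho_ion_model` (fresh from [build_ion_model()] or
#'   pretrained).
#' @param data List with `peptides` (list of `ModifiedPeptide` or
#'   compact strings), `charges` (integer vector) and `targets` (list of
#'   L x 8 matrices with -1 sentinels).
#' @param cfg A [train_config()].
#' @param val Optional validation data in the same shape; defaults to
#'   `data` (overfitting experiments).
#' @return The model with trained `weights`, `history` (epoch, loss, lr,
#'   validation metric) and `val_metric` (best median PCC).
#' @export
train_ion_model <- function(model, data, cfg = train_config(), val = NULL) {
  stopifnot(inherits(model, "phospho_ion_model"))
  if (is.null(val)) val <- data
  mcfg <- model$cfg
  peptides <- lapply(data$peptides, as_peptide)
  tokens <- tokens_matrix(peptides, mcfg$max_len)
  prep <- prepare_ion_batch(peptides, data$targets, mcfg$max_len)
  weights <- model$weights
  state <- adam_state(weights)
  set.seed(cfg$seed)
  n <- length(peptides)
  best <- list(metric = -Inf, weights = weights)
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     val_metric = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- current_lr(cfg, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      S <- mcfg$max_len + 1L
      rowsel <- as.vector(vapply(idx, function(b)
        (b - 1L) * S + seq_len(S), integer(S)))
      tape <- ad_tape()
      wn <- lapply(weights, function(w) ad_leaf(tape, w))
      out <- ion_forward(tape, wn, mcfg, tokens[idx, , drop = FALSE],
                         data$charges[idx])
      loss <- ad_masked_mse(tape, out, prep$target[rowsel, , drop = FALSE],
                            prep$mask[rowsel, , drop = FALSE])
      if (!is.finite(loss$val))
        stop("training diverged: non-finite loss at epoch ", epoch)
      ad_backward(tape, loss)
      grads <- lapply(wn, function(nd)
        if (is.null(nd$grad)) nd$val * 0 else nd$grad)
      upd <- adam_step(weights, grads, state, lr)
      weights <- upd$weights; state <- upd$state
      ep_loss <- ep_loss + loss$val; nb <- nb + 1L
    }
    vm <- NA_real_
    if (epoch %% cfg$eval_every == 0L || epoch == cfg$max_epochs) {
      tmp <- model; tmp$weights <- weights
      preds <- predict_ion(tmp, val$peptides, val$charges)
      vm <- median_summary(mapply(pearson_cc, preds, val$targets))$median
      if (vm > best$metric) best <- list(metric = vm, weights = weights)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / nb,
                                   lr = lr, val_metric = vm))
  }
  model$weights <- best$weights
  model$val_metric <- best$metric
  model$history <- hist
  model$provenance <- if (identical(model$provenance, "initialized"))
    "trained" else "fine-tuned"
  model
}

#' Train (or fine-tune) the RT ensemble
#'
#' Each member is trained independently with the RMSE loss on normalized
#' RT; validation uses the ensemble delta-t95 (minimized). Best-on-
#' validation weights are kept per training run.
#'
#' @param model A `phospho_rt_ensemble`.
#' @param data List with `peptides` and `rt` (numeric, RT units).
#' @param cfg A [train_config()].
#' @param val Optional validation data; defaults to `data`.
#' @return The ensemble with trained members, `history` and `val_metric`
#'   (best ensemble delta-t95 in RT units).
#' @export
train_rt_ensemble <- function(model, data, cfg = train_config(), val = NULL) {
  stopifnot(inherits(model, "phospho_rt_ensemble"))
  if (is.null(val)) val <- data
  mcfg <- model$cfg
  sc <- model$scale
  peptides <- lapply(data$peptides, as_peptide)
  tokens <- tokens_matrix(peptides, mcfg$max_len)
  z <- (data$rt - sc$rt_min) / (sc$rt_max - sc$rt_min)
  n <- length(peptides)
  members <- model$members
  states <- lapply(members, function(m) adam_state(m$weights))
  set.seed(cfg$seed)
  best <- list(metric = Inf, members = members)
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     val_metric = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- current_lr(cfg, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      for (mi in seq_along(members)) {
        tape <- ad_tape()
        wn <- lapply(members[[mi]]$weights, function(w) ad_leaf(tape, w))
        out <- rt_member_forward(tape, wn, mcfg, members[[mi]]$depth,
                                 tokens[idx, , drop = FALSE])
        loss <- ad_rmse(tape, out, matrix(z[idx], ncol = 1L))
        if (!is.finite(loss$val))
          stop("training diverged: non-finite loss at epoch ", epoch)
        ad_backward(tape, loss)
        grads <- lapply(wn, function(nd)
          if (is.null(nd$grad)) nd$val * 0 else nd$grad)
        upd <- adam_step(members[[mi]]$weights, grads, states[[mi]], lr)
        members[[mi]]$weights <- upd$weights
        states[[mi]] <- upd$state
        ep_loss <- ep_loss + loss$val; nb <- nb + 1L
      }
    }
    vm <- NA_real_
    if (epoch %% cfg$eval_every == 0L || epoch == cfg$max_epochs) {
      tmp <- model; tmp$members <- members
      pr <- predict_rt(tmp, val$peptides)
      vm <- delta_t95(pr, val$rt)
      if (vm < best$metric) best <- list(metric = vm, members = members)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / nb,
                                   lr = lr, val_metric = vm))
  }
  model$members <- best$members
  model$val_metric <- best$metric
  model$history <- hist
  model$provenance <- if (identical(model$provenance, "initialized"))
    "trained" else "fine-tuned"
  model
}

# ---- prediction ----------------------------------------------------------

#' Predict fragment-ion intensities
#'
#' Runs the ion model in evaluation mode. Outputs are post-processed:
#' cells impossible for the peptide are forced to -1, valid cells are
#' clipped to `[0, 1]` and renormalized so the maximum valid cell is 1.
#'
#' @param model Trained `phospho_ion_model`.
#' @param peptides List of peptides (objects or compact strings).
#' @param charges Integer vector of precursor charges.
#' @return List of `max_len x 8` fragment matrices.
#' @export
predict_ion <- function(model, peptides, charges) {
  peptides <- lapply(peptides, as_peptide)
  tokens <- tokens_matrix(peptides, model$cfg$max_len)
  tape <- ad_tape()
  wn <- lapply(model$weights, function(w) ad_leaf(tape, w))
  out <- ion_forward(tape, wn, model$cfg, tokens, charges)
  postprocess_ion(out$val, peptides, model$cfg$max_len)
}

#' Predict indexed retention time
#'
#' Ensemble mean of the member predictions on the normalized scale,
#' mapped back to RT units via the model's [rt_scale()].
#'
#' @param model Trained `phospho_rt_ensemble`.
#' @param peptides List of peptides (objects or compact strings).
#' @return Numeric vector of predicted iRT values.
#' @export
predict_rt <- function(model, peptides) {
  peptides <- lapply(peptides, as_peptide)
  tokens <- tokens_matrix(peptides, model$cfg$max_len)
  zs <- vapply(model$members, function(m) {
    tape <- ad_tape()
    wn <- lapply(m$weights, function(w) ad_leaf(tape, w))
    as.vector(rt_member_forward(tape, wn, model$cfg, m$depth, tokens)$val)
  }, numeric(length(peptides)))
  z <- if (is.matrix(zs)) rowMeans(zs) else mean(zs)
  z * (model$scale$rt_max - model$scale$rt_min) + model$scale$rt_min
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the config, weights, provenance and validation
#' metric, so training can resume or transfer.
#'
#' @param model Model or ensemble handle.
#' @param path File path (`.rds`).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`:
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
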