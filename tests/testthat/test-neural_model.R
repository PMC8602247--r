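test_that("ion model forward has the contracted shape and determinism", {
  prec <- random_peptides(3, seed = 401, len = c(7, 10))
  m1 <- build_ion_model(reduced_ion_config(max_len = 12), seed = 5)
  m2 <- build_ion_model(reduced_ion_config(max_len = 12), seed = 5)
  p1 <- predict_ion(m1, prec$modified_peptide, prec$charge)
  p2 <- predict_ion(m2, prec$modified_peptide, prec$charge)
  expect_length(p1, 3)
  for (m in p1) expect_equal(dim(m), c(12L, 8L))
  expect_equal(p1, p2)                      # same seed, same weights
  # repeated prediction from one checkpoint is deterministic
  expect_equal(predict_ion(m1, prec$modified_peptide, prec$charge), p1)
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 2)
  p3 <- predict_ion(m1, prec$modified_peptide[perm], prec$charge[perm])
  expect_equal(p3, p1[perm])
})

test_that("predicted matrices respect the validity mask post-processing", {
  prec <- random_peptides(5, seed = 402, len = c(7, 10))
  mdl <- build_ion_model(reduced_ion_config(max_len = 12), seed = 1)
  preds <- predict_ion(mdl, prec$modified_peptide, prec$charge)
  for (i in seq_along(preds)) {
    msk <- validity_mask(prec$modified_peptide[i], 12)
    expect_true(all(preds[[i]][!msk] == -1))
    expect_true(all(preds[[i]][msk] >= 0 & preds[[i]][msk] <= 1))
    if (any(preds[[i]][msk] > 0)) expect_equal(max(preds[[i]][msk]), 1)
  }
  # phospho-free peptide: loss channels all -1
  pf <- predict_ion(mdl, list("@ALKGDEF"), 2L)[[1]]
  loss_cols <- which(ion_channels()$loss == "H3PO4")
  expect_true(all(pf[, loss_cols] == -1))
})

test_that("rt ensemble averages member outputs and rescales z", {
  prec <- random_peptides(4, seed = 403, len = c(7, 10))
  ens <- build_rt_ensemble(reduced_rt_config(max_len = 12,
                                             ensemble_depths = c(1, 2)), seed = 3)
  full <- predict_rt(ens, prec$modified_peptide)
  sc <- ens$scale
  members <- lapply(seq_along(ens$members), function(i) {
    one <- ens; one$members <- ens$members[i]
    predict_rt(one, prec$modified_peptide)
  })
  expect_equal(full, (members[[1]] + members[[2]]) / 2, tolerance = 1e-12)
  # single-member ensemble equals that member
  one <- ens; one$members <- ens$members[1]
  expect_equal(predict_rt(one, prec$modified_peptide), members[[1]])
  # z = 0.5 maps to RT 50 under the default (-100, 200) scale
  expect_equal(0.5 * (sc$rt_max - sc$rt_min) + sc$rt_min, 50)
  expect_error(build_rt_ensemble(rt_model_config(ensemble_depths = integer())),
               "ensemble_depths")
})

test_that("masked MSE ignores sentinel cells exactly", {
  tg <- matrix(-1, 3, 8)
  tg[1, 1] <- 1.0
  pd <- matrix(0, 3, 8)
  pd[1, 1] <- 0.5
  expect_equal(masked_mse(pd, tg), 0.25)
  expect_equal(masked_mse(tg, tg), 0)
  pd2 <- pd; pd2[2, 5] <- 123              # a -1 cell
  expect_equal(masked_mse(pd2, tg), masked_mse(pd, tg))
  expect_error(masked_mse(matrix(0, 2, 8), matrix(-1, 2, 8)), "no valid cells")
  # the training-loss gradient at -1 cells is exactly zero
  tape <- phosphoDIA:::ad_tape()
  pn <- phosphoDIA:::ad_leaf(tape, pd)
  mask <- (tg != -1) * 1
  tgz <- tg * mask
  loss <- phosphoDIA:::ad_masked_mse(tape, pn, tgz, mask)
  phosphoDIA:::ad_backward(tape, loss)
  expect_true(all(pn$grad[tg == -1] == 0))
  expect_equal(pn$grad[1, 1], 2 * (0.5 - 1.0) / 1)
})

test_that("rt loss is the RMSE with its basic identities", {
  expect_equal(rt_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rt_loss(c(1, -1, 1), c(0, 0, 0)), 1)       # all errors +-e
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  expect_gte(rt_loss(a, b), mean(abs(a - b)))             # RMSE >= MAE
  expect_error(rt_loss(numeric(), numeric()), "empty")
})

test_that("autodiff gradients match finite differences on a tiny ion model", {
  prec <- random_peptides(2, seed = 405, len = c(7, 8))
  cfg <- ion_model_config(aa_embed_dim = 6, charge_embed_dim = 4,
                          lstm_hidden = 5, lstm_layers = 1, d_model = 6,
                          encoder_layers = 1, attention_heads = 2,
                          ffn_dim = 8, max_len = 9)
  mdl <- build_ion_model(cfg, seed = 2)
  peps <- lapply(prec$modified_peptide, phosphoDIA:::as_peptide)
  tokens <- phosphoDIA:::tokens_matrix(peps, cfg$max_len)
  sp <- gen_ground_truth_spectra(prec, synth_config(seed = 405, n_peptides = 2,
                                                    spectrum_noise_sd = 0), L = 9)
  prep <- phosphoDIA:::prepare_ion_batch(peps, sp, cfg$max_len)
  loss_at <- function(w) {
    tape <- phosphoDIA:::ad_tape()
    wn <- lapply(w, function(x) phosphoDIA:::ad_leaf(tape, x))
    out <- phosphoDIA:::ion_forward(tape, wn, cfg, tokens, prec$charge)
    phosphoDIA:::ad_masked_mse(tape, out, prep$target, prep$mask)$val
  }
  tape <- phosphoDIA:::ad_tape()
  wn <- lapply(mdl$weights, function(x) phosphoDIA:::ad_leaf(tape, x))
  out <- phosphoDIA:::ion_forward(tape, wn, cfg, tokens, prec$charge)
  loss <- phosphoDIA:::ad_masked_mse(tape, out, prep$target, prep$mask)
  phosphoDIA:::ad_backward(tape, loss)
  eps <- 1e-6
  set.seed(1)
  for (nm in c("E_aa", "lstm1_f_Wx", "lstm1_b_Wh", "proj_W", "enc1_Wq",
               "enc1_W1", "enc1_ln1_g", "out_W", "out_b")) {
    w <- mdl$weights
    k <- sample(length(w[[nm]]), 1)
    wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
    wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
    fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    an <- wn[[nm]]$grad[k]
    expect_equal(an, fd, tolerance = 1e-4)
  }
})

test_that("dataset splitting groups charge states and honors ratios", {
  seqs <- sprintf("@PEPT%03dIDEK", 1:1000)
  sp <- split_dataset(seqs, c(0.8, 0.1, 0.1), seed = 42)
  expect_equal(lengths(sp), c(train = 800L, val = 100L, test = 100L))
  expect_equal(sort(unname(unlist(sp))), 1:1000)   # disjoint + exhaustive
  # charge states of one peptide never straddle splits
  seqs2 <- rep(sprintf("@PEPT%03dIDEK", 1:50), each = 2)
  sp2 <- split_dataset(seqs2, c(0.8, 0.1, 0.1), seed = 7)
  for (part in sp2) {
    expect_true(all(table(seqs2[part]) == 2))
  }
  expect_identical(split_dataset(seqs, seed = 5), split_dataset(seqs, seed = 5))
  expect_false(identical(split_dataset(seqs, seed = 5),
                         split_dataset(seqs, seed = 6)))
  expect_error(split_dataset(c("@AK", "@AK"), c(0.8, 0.1, 0.1)), "fewer")
})

test_that("short training drives the loss down and keeps the best checkpoint", {
  prec <- random_peptides(12, seed = 406, len = c(7, 9))
  sp <- gen_ground_truth_spectra(prec, synth_config(seed = 406, n_peptides = 12,
                                                    spectrum_noise_sd = 0), L = 10)
  mdl <- build_ion_model(reduced_ion_config(max_len = 10), seed = 1)
  tr <- train_ion_model(mdl, list(peptides = prec$modified_peptide,
                                  charges = prec$charge, targets = sp),
                        train_config(max_epochs = 40, batch_size = 12,
                                     learning_rate = 1e-3, eval_every = 10,
                                     seed = 1))
  h <- tr$history
  expect_lt(mean(tail(h$loss, 5)), mean(head(h$loss, 5)))  # smoothed trend
  evals <- h$val_metric[!is.na(h$val_metric)]
  expect_equal(tr$val_metric, max(evals))   # best, not last
  expect_identical(tr$provenance, "trained")
  # fine-tuning starts from given weights and flags provenance
  ft <- train_ion_model(tr, list(peptides = prec$modified_peptide,
                                 charges = prec$charge, targets = sp),
                        train_config(max_epochs = 2, batch_size = 12,
                                     eval_every = 1, seed = 2))
  expect_identical(ft$provenance, "fine-tuned")
})

test_that("checkpoints save and load round-trip", {
  mdl <- build_ion_model(reduced_ion_config(max_len = 8), seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(mdl, f)
  back <- load_checkpoint(f)
  expect_equal(back$weights, mdl$weights)
  expect_equal(back$cfg, mdl$cfg)
})
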