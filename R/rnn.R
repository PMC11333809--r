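#' Configuration of the MCIF-net recurrent curve-correction network
#'
#' A stacked recurrent network mapping a normalized image-derived input
#' function (IDIF) sequence to the model-corrected input function (MCIF):
#' LSTM blocks of increasing width interleaved with one bidirectional GRU
#' block, dropout between blocks, and a per-time-step affine (time
#' distributed dense) output head. Trained with mean squared error and the
#' Adam optimizer. Defaults follow the reference architecture: LSTM widths
#' 50 -> 100 -> 200 with a 100-unit bidirectional GRU, dropout 0.2, batch
#' size 32.
#'
#' @param time_steps Sequence length (default 38 frames).
#' @param lstm_units Integer vector of LSTM widths (default `c(50,100,200)`).
#'   The bidirectional GRU block is inserted before the last LSTM block.
#' @param bigru_units Units per direction of the bidirectional GRU
#'   (default 100).
#' @param dropout Dropout rate between blocks (default 0.2).
#' @param epochs Training epochs (default 1000).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience in epochs (default 25).
#' @param seed Integer seed.
#' @return An `mcif_net_config`.
#' @export
mcif_net_config <- function(time_steps = 38, lstm_units = c(50, 100, 200),
                            bigru_units = 100, dropout = 0.2, epochs = 1000,
                            batch_size = 32, learning_rate = 1e-3,
                            patience = 25, seed = 1) {
  stopifnot(time_steps >= 2, all(lstm_units >= 1), bigru_units >= 1,
            dropout >= 0, dropout < 1)
  structure(list(time_steps = as.integer(time_steps),
                 lstm_units = as.integer(lstm_units),
                 bigru_units = as.integer(bigru_units), dropout = dropout,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "mcif_net_config")
}

rnn_layer_specs <- function(cfg) {
  specs <- list()
  nl <- length(cfg$lstm_units)
  add <- function(specs, type, units) c(specs, list(list(type = type, units = units)))
  if (nl > 1) {
    for (u in cfg$lstm_units[seq_len(nl - 1)]) specs <- add(specs, "lstm", u)
    specs <- add(specs, "bigru", cfg$bigru_units)
    specs <- add(specs, "lstm", cfg$lstm_units[nl])
  } else {
    specs <- add(specs, "lstm", cfg$lstm_units[1])
    specs <- add(specs, "bigru", cfg$bigru_units)
  }
  specs
}

init_lstm <- function(d, u) {
  list(W = glorot_init(d, 4 * u), U = glorot_init(u, 4 * u), b = {
    b <- numeric(4 * u); b[u + seq_len(u)] <- 1; b  # forget-gate bias 1
  })
}

init_gru <- function(d, u) {
  list(W = glorot_init(d, 3 * u), U = glorot_init(u, 3 * u), b = numeric(3 * u))
}

#' Build (initialize) an MCIF-net model
#'
#' @param cfg An [mcif_net_config].
#' @return An `mcif_net_model` with initialized parameters.
#' @export
build_mcif_net <- function(cfg) {
  stopifnot(inherits(cfg, "mcif_net_config"))
  set.seed(cfg$seed)
  specs <- rnn_layer_specs(cfg)
  p <- list()
  din <- 1L
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$type == "lstm") {
      lp <- init_lstm(din, sp$units)
      dout <- sp$units
    } else {
      lp <- list(fwd = init_gru(din, sp$units), bwd = init_gru(din, sp$units))
      dout <- 2L * sp$units
    }
    for (nm in names(lp)) {
      if (is.list(lp[[nm]])) {
        for (nm2 in names(lp[[nm]])) p[[paste0("l", i, "_", nm, "_", nm2)]] <- lp[[nm]][[nm2]]
      } else {
        p[[paste0("l", i, "_", nm)]] <- lp[[nm]]
      }
    }
    din <- dout
  }
  p[["dense_W"]] <- glorot_init(din, 1L)
  p[["dense_b"]] <- 0
  structure(list(cfg = cfg, specs = specs, params = p), class = "mcif_net_model")
}

# X: array (batch, T, d). Returns (batch, T, u) plus caches for BPTT.
lstm_fwd <- function(X, W, U, b) {
  bsz <- dim(X)[1]; Tn <- dim(X)[2]; u <- ncol(U) / 4
  H <- matrix(0, bsz, u); C <- matrix(0, bsz, u)
  out <- array(0, dim = c(bsz, Tn, u))
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], nrow = bsz)
    zbar <- Xt %*% W + H %*% U + matrix(b, bsz, 4 * u, byrow = TRUE)
    i <- sigmoid(zbar[, seq_len(u), drop = FALSE])
    f <- sigmoid(zbar[, u + seq_len(u), drop = FALSE])
    g <- tanh(zbar[, 2 * u + seq_len(u), drop = FALSE])
    o <- sigmoid(zbar[, 3 * u + seq_len(u), drop = FALSE])
    Cprev <- C; Hprev <- H
    C <- f * C + i * g
    tc <- tanh(C)
    H <- o * tc
    out[, t, ] <- H
    cache[[t]] <- list(Xt = Xt, Hprev = Hprev, Cprev = Cprev,
                       i = i, f = f, g = g, o = o, tc = tc)
  }
  list(out = out, cache = cache)
}

lstm_bwd <- function(dOut, cache, W, U) {
  Tn <- dim(dOut)[2]; bsz <- dim(dOut)[1]; u <- ncol(U) / 4
  gW <- W * 0; gU <- U * 0; gb <- numeric(4 * u)
  dX <- array(0, dim = c(bsz, Tn, nrow(W)))
  dh_next <- matrix(0, bsz, u); dc_next <- matrix(0, bsz, u)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- matrix(dOut[, t, ], nrow = bsz) + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$Cprev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    gW <- gW + crossprod(cc$Xt, dz)
    gU <- gU + crossprod(cc$Hprev, dz)
    gb <- gb + colSums(dz)
    dX[, t, ] <- dz %*% t(W)
    dh_next <- dz %*% t(U)
  }
  list(dX = dX, gW = gW, gU = gU, gb = gb)
}

gru_fwd <- function(X, W, U, b, reverse = FALSE) {
  bsz <- dim(X)[1]; Tn <- dim(X)[2]; u <- ncol(U) / 3
  H <- matrix(0, bsz, u)
  out <- array(0, dim = c(bsz, Tn, u))
  cache <- vector("list", Tn)
  ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  for (t in ts) {
    Xt <- matrix(X[, t, ], nrow = bsz)
    zx <- Xt %*% W + matrix(b, bsz, 3 * u, byrow = TRUE)
    hu <- H %*% U
    z <- sigmoid(zx[, seq_len(u), drop = FALSE] + hu[, seq_len(u), drop = FALSE])
    r <- sigmoid(zx[, u + seq_len(u), drop = FALSE] + hu[, u + seq_len(u), drop = FALSE])
    hn <- hu[, 2 * u + seq_len(u), drop = FALSE]
    n <- tanh(zx[, 2 * u + seq_len(u), drop = FALSE] + r * hn)
    Hprev <- H
    H <- (1 - z) * n + z * H
    out[, t, ] <- H
    cache[[t]] <- list(Xt = Xt, Hprev = Hprev, z = z, r = r, n = n, hn = hn)
  }
  list(out = out, cache = cache)
}

gru_bwd <- function(dOut, cache, W, U, reverse = FALSE) {
  Tn <- dim(dOut)[2]; bsz <- dim(dOut)[1]; u <- ncol(U) / 3
  gW <- W * 0; gU <- U * 0; gb <- numeric(3 * u)
  dX <- array(0, dim = c(bsz, Tn, nrow(W)))
  dh_next <- matrix(0, bsz, u)
  ts <- if (reverse) seq_len(Tn) else rev(seq_len(Tn))
  for (t in ts) {
    cc <- cache[[t]]
    dh <- matrix(dOut[, t, ], nrow = bsz) + dh_next
    dn <- dh * (1 - cc$z)
    dz <- dh * (cc$Hprev - cc$n)
    dhprev <- dh * cc$z
    dnpre <- dn * (1 - cc$n^2)
    dr <- dnpre * cc$hn
    dzpre <- dz * cc$z * (1 - cc$z)
    drpre <- dr * cc$r * (1 - cc$r)
    dgates <- cbind(dzpre, drpre, dnpre)
    gW <- gW + crossprod(cc$Xt, dgates)
    gb <- gb + colSums(dgates)
    # U gradient: n-gate path is gated by r
    gU <- gU + crossprod(cc$Hprev, cbind(dzpre, drpre, dnpre * cc$r))
    dhprev <- dhprev + dzpre %*% t(U[, seq_len(u), drop = FALSE]) +
      drpre %*% t(U[, u + seq_len(u), drop = FALSE]) +
      (dnpre * cc$r) %*% t(U[, 2 * u + seq_len(u), drop = FALSE])
    dX[, t, ] <- dgates %*% t(W)
    dh_next <- dhprev
  }
  list(dX = dX, gW = gW, gU = gU, gb = gb)
}

mcif_net_forward <- function(model, X, train = FALSE, dropout_seed = NULL) {
  p <- model$params
  cfg <- model$cfg
  bsz <- dim(X)[1]
  cur <- X
  caches <- list()
  if (train && !is.null(dropout_seed)) set.seed(dropout_seed)
  for (i in seq_along(model$specs)) {
    sp <- model$specs[[i]]
    pre <- paste0("l", i, "_")
    if (sp$type == "lstm") {
      fw <- lstm_fwd(cur, p[[paste0(pre, "W")]], p[[paste0(pre, "U")]],
                     p[[paste0(pre, "b")]])
      out <- fw$out
      caches[[i]] <- list(type = "lstm", cache = fw$cache, input = cur)
    } else {
      f1 <- gru_fwd(cur, p[[paste0(pre, "fwd_W")]], p[[paste0(pre, "fwd_U")]],
                    p[[paste0(pre, "fwd_b")]], reverse = FALSE)
      f2 <- gru_fwd(cur, p[[paste0(pre, "bwd_W")]], p[[paste0(pre, "bwd_U")]],
                    p[[paste0(pre, "bwd_b")]], reverse = TRUE)
      u <- sp$units
      out <- array(0, dim = c(bsz, dim(cur)[2], 2 * u))
      out[, , seq_len(u)] <- f1$out
      out[, , u + seq_len(u)] <- f2$out
      caches[[i]] <- list(type = "bigru", c1 = f1$cache, c2 = f2$cache,
                          input = cur)
    }
    if (train && cfg$dropout > 0) {
      keep <- array(stats::runif(length(out)) >= cfg$dropout, dim = dim(out))
      out <- out * keep / (1 - cfg$dropout)
      caches[[i]]$drop <- keep
    }
    cur <- out
  }
  d <- dim(cur)
  flat <- matrix(cur, nrow = d[1] * d[2])
  pred <- matrix(flat %*% p[["dense_W"]] + p[["dense_b"]], d[1], d[2])
  list(pred = pred, head_in = cur, caches = caches)
}

mcif_net_backward <- function(model, fw, dPred) {
  p <- model$params
  cfg <- model$cfg
  g <- list()
  d <- dim(fw$head_in)
  flat <- matrix(fw$head_in, nrow = d[1] * d[2])
  dvec <- as.vector(dPred)
  g[["dense_W"]] <- crossprod(flat, dvec)
  g[["dense_b"]] <- sum(dvec)
  dcur <- array(dvec %*% t(p[["dense_W"]]), dim = d)
  for (i in rev(seq_along(model$specs))) {
    sp <- model$specs[[i]]
    pre <- paste0("l", i, "_")
    cc <- fw$caches[[i]]
    if (!is.null(cc$drop)) dcur <- dcur * cc$drop / (1 - cfg$dropout)
    if (cc$type == "lstm") {
      bk <- lstm_bwd(dcur, cc$cache, p[[paste0(pre, "W")]], p[[paste0(pre, "U")]])
      g[[paste0(pre, "W")]] <- bk$gW
      g[[paste0(pre, "U")]] <- bk$gU
      g[[paste0(pre, "b")]] <- bk$gb
      dcur <- bk$dX
    } else {
      u <- sp$units
      b1 <- gru_bwd(dcur[, , seq_len(u), drop = FALSE], cc$c1,
                    p[[paste0(pre, "fwd_W")]], p[[paste0(pre, "fwd_U")]], FALSE)
      b2 <- gru_bwd(dcur[, , u + seq_len(u), drop = FALSE], cc$c2,
                    p[[paste0(pre, "bwd_W")]], p[[paste0(pre, "bwd_U")]], TRUE)
      g[[paste0(pre, "fwd_W")]] <- b1$gW; g[[paste0(pre, "fwd_U")]] <- b1$gU
      g[[paste0(pre, "fwd_b")]] <- b1$gb
      g[[paste0(pre, "bwd_W")]] <- b2$gW; g[[paste0(pre, "bwd_U")]] <- b2$gU
      g[[paste0(pre, "bwd_b")]] <- b2$gb
      dcur <- b1$dX + b2$dX
    }
  }
  g
}

#' Train MCIF-net on normalized IDIF -> MCIF sequence pairs
#'
#' @param X,Y Numeric matrices `n_samples x time_steps` of normalized input
#'   (IDIF) and target (MCIF) sequences.
#' @param cfg An [mcif_net_config].
#' @param X_val,Y_val Optional validation pairs for early stopping and
#'   best-checkpoint restore.
#' @param verbose Print per-epoch losses.
#' @return A trained `mcif_net_model` with a `history` element.
#' @export
train_mcif_net <- function(X, Y, cfg, X_val = NULL, Y_val = NULL,
                           verbose = FALSE) {
  stopifnot(is.matrix(X), all(dim(X) == dim(Y)))
  if (ncol(X) != cfg$time_steps) {
    stop(sprintf("sequences have %d steps but config expects %d",
                 ncol(X), cfg$time_steps), call. = FALSE)
  }
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  model <- build_mcif_net(cfg)
  opt <- adam_state(model$params)
  best <- list(loss = Inf, params = model$params)
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  wait <- 0L
  set.seed(cfg$seed + 1L)
  n <- nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    tr <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- array(X[idx, , drop = FALSE], dim = c(length(idx), cfg$time_steps, 1))
      Yb <- Y[idx, , drop = FALSE]
      fw <- mcif_net_forward(model, Xb, train = TRUE,
                             dropout_seed = cfg$seed + ep * 1000L + start)
      err <- fw$pred - Yb
      tr <- tr + mean(err^2); nb <- nb + 1
      grads <- mcif_net_backward(model, fw, 2 * err / length(err))
      upd <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
    tr <- tr / nb
    vl <- NA_real_
    if (!is.null(X_val)) {
      vl <- mcif_net_mse(model, X_val, Y_val)
      if (vl < best$loss) { best <- list(loss = vl, params = model$params); wait <- 0L }
      else wait <- wait + 1L
    }
    history <- rbind(history, data.frame(epoch = ep, train_mse = tr, val_mse = vl))
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d: train MSE %.5f val MSE %.5f", ep, tr, vl))
    if (!is.null(X_val) && wait >= cfg$patience) break
  }
  if (is.finite(best$loss)) model$params <- best$params
  model$history <- history
  model
}

mcif_net_mse <- function(model, X, Y) {
  pred <- predict_mcif_matrix(model, X)
  mean((pred - Y)^2)
}

#' @rdname train_mcif_net
#' @param model A trained `mcif_net_model`.
#' @export
predict_mcif_matrix <- function(model, X) {
  Xb <- array(X, dim = c(nrow(X), ncol(X), 1))
  mcif_net_forward(model, Xb, train = FALSE)$pred
}

#' Predict the model-corrected input function from an IDIF curve
#'
#' The curve is min-max normalized, passed through the network and
#' de-normalized with the input curve's own scale (per-sample scaling), so
#' the output lives on the same Bq/cc scale as the IDIF.
#'
#' @param model A trained `mcif_net_model`.
#' @param idif A [tacurve].
#' @return A [tacurve] labelled `"MCIF"`.
#' @export
predict_mcif <- function(model, idif) {
  stopifnot(inherits(idif, "tacurve"))
  xn <- normalize_curve(idif)
  pred <- predict_mcif_matrix(model, matrix(xn$values, nrow = 1))
  sc <- attr(xn, "scale")
  # an input function is non-negative; clip linear-head undershoot
  tacurve(pmax(pred[1, ] * (sc[2] - sc[1]) + sc[1], 0), idif$times_s,
          label = "MCIF")
}

#' Sample-wise k-fold cross-validation of MCIF-net
#'
#' Mirrors the reporting of the reference evaluation: per-fold train loss,
#' validation loss/MSE, MAE and RMSE on the normalized scale, plus mean/SD.
#'
#' @param X,Y Normalized sequence matrices (`n x time_steps`).
#' @param k Number of folds (default 5).
#' @param cfg An [mcif_net_config].
#' @param verbose Print progress.
#' @return List: `folds` data.frame, `summary` (mean/SD rows), `models`.
#' @export
crossvalidate_mcif_net <- function(X, Y, k = 5, cfg, verbose = FALSE) {
  n <- nrow(X)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  set.seed(cfg$seed)
  fold_of <- sample(rep(seq_len(k), length.out = n))
  rows <- list(); models <- list()
  for (fold in seq_len(k)) {
    tr <- fold_of != fold
    model <- train_mcif_net(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], cfg,
                            X_val = X[!tr, , drop = FALSE],
                            Y_val = Y[!tr, , drop = FALSE], verbose = verbose)
    models[[fold]] <- model
    pred <- predict_mcif_matrix(model, X[!tr, , drop = FALSE])
    err <- pred - Y[!tr, , drop = FALSE]
    rows[[fold]] <- data.frame(
      fold = fold,
      train_loss = utils::tail(model$history$train_mse, 1),
      val_loss = mean(err^2), val_mse = mean(err^2),
      val_mae = mean(abs(err)), val_rmse = sqrt(mean(err^2)))
  }
  tab <- do.call(rbind, rows)
  num <- tab[, -1]
  summary <- rbind(colMeans(num), apply(num, 2, stats::sd))
  rownames(summary) <- c("mean", "sd")
  list(folds = tab, summary = as.data.frame(summary), models = models)
}
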