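#' Configuration of the carotid-segmentation 3D U-Net (ICA-net)
#'
#' An encoder/decoder with skip connections: `depth` resolution stages, two
#' 3x3x3 convolutions per stage, filter counts starting at `base_filters`
#' and doubling per downsampling step up to `max_filters`, max pooling and
#' nearest-neighbour upsampling, and a squeeze-and-excitation (SE) channel
#' gate after each encoder stage. Trained with the combined Dice + binary
#' cross-entropy loss ([combined_loss()]) and the Adam optimizer, with early
#' stopping on validation loss and best-checkpoint restore.
#'
#' @param input_shape Spatial input shape; each axis must be divisible by
#'   `2^(depth-1)`.
#' @param depth Number of resolution stages (default 5).
#' @param base_filters Filters in the first stage (default 64).
#' @param max_filters Cap on the filter doubling (default 512).
#' @param se_reduction SE bottleneck reduction ratio (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 50).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param prob_threshold Probability cutoff for mask binarization
#'   (default 0.5).
#' @param smooth Dice smoothing constant (default 1e-5).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `unet_config`.
#' @export
unet_config <- function(input_shape = c(64, 64, 64), depth = 5,
                        base_filters = 64, max_filters = 512,
                        se_reduction = 16, learning_rate = 1e-3,
                        epochs = 50, patience = 5, prob_threshold = 0.5,
                        smooth = 1e-5, seed = 1) {
  stopifnot(depth >= 2, base_filters >= 1)
  if (any(input_shape %% 2^(depth - 1) != 0)) {
    stop(sprintf("input shape must be divisible by 2^(depth-1) = %d",
                 2^(depth - 1)), call. = FALSE)
  }
  structure(list(input_shape = as.integer(input_shape), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 max_filters = as.integer(max_filters),
                 se_reduction = as.integer(se_reduction),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 prob_threshold = prob_threshold, smooth = smooth,
                 seed = as.integer(seed)),
            class = "unet_config")
}

unet_channels <- function(cfg) {
  pmin(cfg$base_filters * 2^(seq_len(cfg$depth) - 1), cfg$max_filters)
}

#' Build (initialize) a U-Net model from its configuration
#'
#' @param cfg A [unet_config].
#' @return A `unet_model`: the configuration plus He-initialized parameters.
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  set.seed(cfg$seed)
  ch <- unet_channels(cfg)
  p <- list()
  conv_par <- function(cin, cout) he_init(27 * cin, cout, 27 * cin)
  for (s in seq_len(cfg$depth)) {
    cin <- if (s == 1) 1L else ch[s - 1]
    p[[paste0("enc", s, "_w1")]] <- conv_par(cin, ch[s])
    p[[paste0("enc", s, "_b1")]] <- numeric(ch[s])
    p[[paste0("enc", s, "_w2")]] <- conv_par(ch[s], ch[s])
    p[[paste0("enc", s, "_b2")]] <- numeric(ch[s])
    if (s < cfg$depth) {  # SE gate on each encoder stage output
      hid <- max(1L, ch[s] %/% cfg$se_reduction)
      p[[paste0("se", s, "_w1")]] <- glorot_init(ch[s], hid)
      p[[paste0("se", s, "_b1")]] <- numeric(hid)
      p[[paste0("se", s, "_w2")]] <- glorot_init(hid, ch[s])
      p[[paste0("se", s, "_b2")]] <- numeric(ch[s])
    }
  }
  for (s in seq_len(cfg$depth - 1)) {
    cin <- ch[s + 1] + ch[s]  # upsampled below + skip
    p[[paste0("dec", s, "_w1")]] <- conv_par(cin, ch[s])
    p[[paste0("dec", s, "_b1")]] <- numeric(ch[s])
    p[[paste0("dec", s, "_w2")]] <- conv_par(ch[s], ch[s])
    p[[paste0("dec", s, "_b2")]] <- numeric(ch[s])
  }
  p[["out_w"]] <- glorot_init(ch[1], 1L)
  p[["out_b"]] <- 0
  structure(list(cfg = cfg, params = p), class = "unet_model")
}

conv_relu <- function(x, w, b) {
  z <- cpp_conv3d_fwd(x, dim(x), w, b)
  a <- pmax(z, 0)
  dim(a) <- dim(z)
  a
}

se_gate <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  flat <- matrix(x, ncol = d[4])
  s <- colMeans(flat)
  h <- pmax(drop(s %*% w1) + b1, 0)
  g <- sigmoid(drop(h %*% w2) + b2)
  list(y = array(flat %*% diag(g, nrow = length(g)), dim = d),
       s = s, h = h, g = g, flat = flat)
}

# full forward pass; when train=TRUE all intermediates are cached
unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  # fully convolutional: any shape divisible by 2^(depth-1) works
  if (any(dim(x) %% 2^(cfg$depth - 1) != 0)) {
    stop(sprintf("input shape must be divisible by 2^(depth-1) = %d",
                 2^(cfg$depth - 1)), call. = FALSE)
  }
  cur <- array(x, dim = c(dim(x), 1L))
  cache <- list(x = cur)
  skips <- list()
  for (s in seq_len(cfg$depth)) {
    a1 <- conv_relu(cur, p[[paste0("enc", s, "_w1")]], p[[paste0("enc", s, "_b1")]])
    a2 <- conv_relu(a1, p[[paste0("enc", s, "_w2")]], p[[paste0("enc", s, "_b2")]])
    if (train) { cache[[paste0("enc", s, "_in")]] <- cur
                 cache[[paste0("enc", s, "_a1")]] <- a1
                 cache[[paste0("enc", s, "_a2")]] <- a2 }
    if (s < cfg$depth) {
      se <- se_gate(a2, p[[paste0("se", s, "_w1")]], p[[paste0("se", s, "_b1")]],
                    p[[paste0("se", s, "_w2")]], p[[paste0("se", s, "_b2")]])
      if (train) cache[[paste0("se", s)]] <- se
      skips[[s]] <- se$y
      pooled <- cpp_maxpool3d(se$y, dim(se$y))
      if (train) cache[[paste0("pool", s, "_idx")]] <- pooled$idx
      if (train) cache[[paste0("pool", s, "_indim")]] <- dim(se$y)
      cur <- pooled$y
    } else {
      cur <- a2
    }
  }
  for (s in rev(seq_len(cfg$depth - 1))) {
    up <- cpp_upsample3d(cur, dim(cur))
    if (train) cache[[paste0("up", s, "_indim")]] <- dim(cur)
    skip <- skips[[s]]
    cat4 <- array(c(up, skip), dim = c(dim(up)[1:3], dim(up)[4] + dim(skip)[4]))
    a1 <- conv_relu(cat4, p[[paste0("dec", s, "_w1")]], p[[paste0("dec", s, "_b1")]])
    a2 <- conv_relu(a1, p[[paste0("dec", s, "_w2")]], p[[paste0("dec", s, "_b2")]])
    if (train) { cache[[paste0("dec", s, "_in")]] <- cat4
                 cache[[paste0("dec", s, "_a1")]] <- a1
                 cache[[paste0("dec", s, "_a2")]] <- a2
                 cache[[paste0("dec", s, "_nup")]] <- dim(up)[4] }
    cur <- a2
  }
  d <- dim(cur)
  flat <- matrix(cur, ncol = d[4])
  z <- drop(flat %*% p[["out_w"]]) + p[["out_b"]]
  prob <- array(sigmoid(z), dim = d[1:3])
  if (train) { cache[["head_in"]] <- cur; cache[["prob"]] <- prob }
  list(prob = prob, cache = cache)
}

# gradient of a conv+relu pair: gz = ga * (a > 0), then conv backward
conv_relu_bwd <- function(x, w, a, ga) {
  gz <- ga * (a > 0)
  dim(gz) <- dim(a)
  cpp_conv3d_bwd(x, dim(x), w, gz)
}

unet_backward <- function(model, cache, dz_out) {
  cfg <- model$cfg
  p <- model$params
  g <- list()
  head_in <- cache[["head_in"]]
  d <- dim(head_in)
  flat <- matrix(head_in, ncol = d[4])
  g[["out_w"]] <- crossprod(flat, as.vector(dz_out))
  g[["out_b"]] <- sum(dz_out)
  gcur <- array(as.vector(dz_out) %*% t(p[["out_w"]]), dim = d)

  gskips <- vector("list", cfg$depth - 1)
  for (s in seq_len(cfg$depth - 1)) {
    a1 <- cache[[paste0("dec", s, "_a1")]]
    a2 <- cache[[paste0("dec", s, "_a2")]]
    cat4 <- cache[[paste0("dec", s, "_in")]]
    b2 <- conv_relu_bwd(a1, p[[paste0("dec", s, "_w2")]], a2, gcur)
    g[[paste0("dec", s, "_w2")]] <- b2$gw; g[[paste0("dec", s, "_b2")]] <- as.numeric(b2$gb)
    b1 <- conv_relu_bwd(cat4, p[[paste0("dec", s, "_w1")]], a1, b2$gx)
    g[[paste0("dec", s, "_w1")]] <- b1$gw; g[[paste0("dec", s, "_b1")]] <- as.numeric(b1$gb)
    nup <- cache[[paste0("dec", s, "_nup")]]
    dcat <- dim(cat4)
    gcat <- b1$gx
    gup <- gcat[, , , seq_len(nup), drop = FALSE]
    gskips[[s]] <- gcat[, , , nup + seq_len(dcat[4] - nup), drop = FALSE]
    gcur <- cpp_upsample3d_bwd(gup, dim(gup))  # gradient into the stage below
  }

  # gcur now holds the gradient at the bottleneck output; walk encoders up
  for (s in rev(seq_len(cfg$depth))) {
    if (s < cfg$depth) {
      gpool <- cpp_maxpool3d_bwd(cache[[paste0("pool", s, "_idx")]], gcur,
                                 cache[[paste0("pool", s, "_indim")]])
      gse_y <- gpool + gskips[[s]]
      se <- cache[[paste0("se", s)]]
      dse <- dim(gse_y)
      gflat <- matrix(gse_y, ncol = dse[4])
      gg <- colSums(gflat * se$flat)                   # d/d gate
      ga2_flat <- gflat %*% diag(se$g, nrow = length(se$g))
      gz2 <- gg * se$g * (1 - se$g)
      g[[paste0("se", s, "_w2")]] <- outer(se$h, gz2)
      g[[paste0("se", s, "_b2")]] <- gz2
      gh <- drop(p[[paste0("se", s, "_w2")]] %*% gz2) * (se$h > 0)
      g[[paste0("se", s, "_w1")]] <- outer(se$s, gh)
      g[[paste0("se", s, "_b1")]] <- gh
      gs <- drop(p[[paste0("se", s, "_w1")]] %*% gh)
      nvox <- nrow(se$flat)
      ga2 <- array(ga2_flat + rep(gs / nvox, each = nvox), dim = dse)
    } else {
      ga2 <- gcur
    }
    a1 <- cache[[paste0("enc", s, "_a1")]]
    a2 <- cache[[paste0("enc", s, "_a2")]]
    xin <- cache[[paste0("enc", s, "_in")]]
    b2 <- conv_relu_bwd(a1, p[[paste0("enc", s, "_w2")]], a2, ga2)
    g[[paste0("enc", s, "_w2")]] <- b2$gw; g[[paste0("enc", s, "_b2")]] <- as.numeric(b2$gb)
    b1 <- conv_relu_bwd(xin, p[[paste0("enc", s, "_w1")]], a1, b2$gx)
    g[[paste0("enc", s, "_w1")]] <- b1$gw; g[[paste0("enc", s, "_b1")]] <- as.numeric(b1$gb)
    gcur <- b1$gx  # only used by the stage above via pooling
  }
  g
}

#' Train the segmentation U-Net
#'
#' Stochastic training with one volume per step, the combined Dice + BCE
#' loss, Adam updates, optional validation-based early stopping and
#' best-checkpoint restore.
#'
#' @param items Training items: each a list with `volume` (3D array, input
#'   intensities) and `mask` (a [mask3d]).
#' @param cfg A [unet_config].
#' @param val_items Optional validation items in the same format.
#' @param verbose Print per-epoch losses.
#' @return A trained `unet_model` with a `history` element (per-epoch train
#'   and validation loss).
#' @export
train_segmenter <- function(items, cfg, val_items = NULL, verbose = FALSE) {
  if (length(items) == 0L) stop("empty training set", call. = FALSE)
  model <- build_unet(cfg)
  opt <- adam_state(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0L
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(items))
    tr_loss <- 0
    for (i in ord) {
      it <- items[[i]]
      fw <- unet_forward(model, it$volume, train = TRUE)
      gmask <- it$mask$data * 1.0
      tr_loss <- tr_loss + combined_loss(gmask, fw$prob, smooth = cfg$smooth)
      dz <- combined_loss_grad_logits(fw$prob, gmask, smooth = cfg$smooth)
      dim(dz) <- dim(fw$prob)
      grads <- unet_backward(model, fw$cache, dz)
      upd <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
    tr_loss <- tr_loss / length(items)
    vl <- NA_real_
    if (!is.null(val_items) && length(val_items) > 0) {
      vl <- mean(vapply(val_items, function(it) {
        fw <- unet_forward(model, it$volume, train = FALSE)
        combined_loss(it$mask$data * 1.0, fw$prob, smooth = cfg$smooth)
      }, numeric(1)))
      if (vl < best$loss) {
        best <- list(loss = vl, params = model$params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = tr_loss,
                                         val_loss = vl))
    if (verbose) message(sprintf("epoch %d: train %.4f val %.4f", ep, tr_loss, vl))
    if (!is.null(val_items) && wait >= cfg$patience) break
  }
  if (is.finite(best$loss)) model$params <- best$params
  model$history <- history
  model
}

#' Predict a binary carotid mask from a 3D frame
#'
#' @param model A trained `unet_model`.
#' @param frame_3d Input 3D array matching the model's input shape.
#' @param prob_threshold Probability cutoff (default the model config's).
#' @return A [mask3d].
#' @export
predict_mask <- function(model, frame_3d, prob_threshold = model$cfg$prob_threshold) {
  fw <- unet_forward(model, frame_3d, train = FALSE)
  mask3d(array(as.integer(fw$prob >= prob_threshold), dim = dim(fw$prob)))
}

#' Subject-grouped fold assignment
#'
#' Randomly assigns each subject to one of `k` folds with balanced sizes, so
#' that no subject's data (including augmented copies, which inherit the
#' subject id) can appear in both the training and validation side of any
#' fold.
#'
#' @param subject_ids Character or integer vector of unique subject ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector mapping subject id to fold in `1..k`.
#' @export
fold_assignment <- function(subject_ids, k = 5, seed = 1) {
  subject_ids <- unique(subject_ids)
  if (length(subject_ids) < k) stop("fewer subjects than folds", call. = FALSE)
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = length(subject_ids)))
  stats::setNames(folds, subject_ids)
}

#' Subject-grouped k-fold cross-validation of the segmentation network
#'
#' Splits subjects into `k` folds, applies augmentation to the training side
#' only (after splitting), trains one model per fold and evaluates Dice and
#' intersection-over-union on the held-out subjects' original (unaugmented)
#' volumes.
#'
#' @param subjects List of items (`volume`, `mask`, `subject_id`).
#' @param k Number of folds (default 5).
#' @param cfg A [unet_config].
#' @param aug_cfg Optional [augment_config] for training-side expansion;
#'   `NULL` trains on the originals only.
#' @param train_transform Optional function `(item, seed) -> item` applied
#'   to training and validation items before training (e.g. a mask-centred
#'   crop via [crop_around_mask()]); the network is fully convolutional, so
#'   held-out Dice/IoU are still computed on the full volumes.
#' @param verbose Print progress.
#' @return List: `folds` (data.frame with per-fold train loss, val loss, val
#'   Dice, val IoU plus mean/SD rows), `models`, `assignment`.
#' @export
crossvalidate <- function(subjects, k = 5, cfg, aug_cfg = NULL,
                          train_transform = NULL, verbose = FALSE) {
  ids <- vapply(subjects, function(s) as.character(s$subject_id), character(1))
  assignment <- fold_assignment(ids, k = k, seed = cfg$seed)
  rows <- list()
  models <- list()
  for (fold in seq_len(k)) {
    val_ids <- names(assignment)[assignment == fold]
    tr_items <- subjects[!(ids %in% val_ids)]
    va_items <- subjects[ids %in% val_ids]
    if (!is.null(aug_cfg)) tr_items <- expand_training_set(tr_items, aug_cfg)
    va_train <- va_items
    if (!is.null(train_transform)) {
      tr_items <- lapply(seq_along(tr_items), function(i)
        train_transform(tr_items[[i]], cfg$seed + 31L * i))
      va_train <- lapply(seq_along(va_items), function(i)
        train_transform(va_items[[i]], cfg$seed + 17L * i))
    }
    model <- train_segmenter(tr_items, cfg, val_items = va_train,
                             verbose = verbose)
    models[[fold]] <- model
    h <- model$history
    dice <- vapply(va_items, function(it) {
      m <- predict_mask(model, it$volume)
      dice_coefficient(it$mask, m$data * 1.0, smooth = cfg$smooth)
    }, numeric(1))
    iou <- vapply(va_items, function(it) {
      m <- predict_mask(model, it$volume)
      jaccard_index(it$mask, m$data * 1.0, smooth = cfg$smooth)
    }, numeric(1))
    vl <- suppressWarnings(min(h$val_loss, na.rm = TRUE))
    rows[[fold]] <- data.frame(fold = fold,
                               train_loss = utils::tail(h$train_loss, 1),
                               val_loss = if (is.finite(vl)) vl else NA_real_,
                               val_dice = mean(dice), val_iou = mean(iou))
    if (verbose) message(sprintf("fold %d: dice %.3f iou %.3f",
                                 fold, mean(dice), mean(iou)))
  }
  tab <- do.call(rbind, rows)
  summary_rows <- data.frame(
    fold = c(NA, NA),
    train_loss = c(mean(tab$train_loss), stats::sd(tab$train_loss)),
    val_loss = c(mean(tab$val_loss), stats::sd(tab$val_loss)),
    val_dice = c(mean(tab$val_dice), stats::sd(tab$val_dice)),
    val_iou = c(mean(tab$val_iou), stats::sd(tab$val_iou)))
  rownames(summary_rows) <- c("mean", "sd")
  list(folds = tab, summary = summary_rows, models = models,
       assignment = assignment)
}
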