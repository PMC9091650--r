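#' Spatial-pyramid-pooling network configuration
#'
#' Defaults follow the reference architecture for 21-column IMF feature
#' maps: conv1 with 10 filters of kernel 10x4 and stride 5x1 (valid in
#' both dimensions), conv2 with 200 filters of kernel 5x2 and stride 1x1
#' (width padded by one column so the width stays 18), pyramid levels
#' [4, 2, 1] giving a fixed 4,200-long vector at 200 channels, and fully
#' connected sizes 500 -> 200 -> 2. Training uses momentum SGD on the
#' softmax cross-entropy.
#'
#' @param conv_channels output channels of the two conv layers.
#' @param conv_kernels list of `c(height, width)` kernels.
#' @param conv_strides list of `c(height, width)` strides.
#' @param conv_pad_w right zero-padding (columns) per conv layer.
#' @param levels pyramid levels `n_l`.
#' @param fc_sizes fully connected layer sizes; last entry is the number
#'   of classes.
#' @param lr,momentum,epochs,batch optimizer hyperparameters.
#' @param seed initialization / shuffling seed.
#' @return list of class `spp_config`.
#' @export
spp_config <- function(conv_channels = c(10L, 200L),
                       conv_kernels = list(c(10L, 4L), c(5L, 2L)),
                       conv_strides = list(c(5L, 1L), c(1L, 1L)),
                       conv_pad_w = c(0L, 1L),
                       levels = c(4L, 2L, 1L),
                       fc_sizes = c(500L, 200L, 2L),
                       lr = 0.01, momentum = 0.9, epochs = 30L,
                       batch = 16L, seed = 1L) {
  stopifnot(length(conv_channels) == length(conv_kernels),
            length(conv_kernels) == length(conv_strides),
            length(conv_pad_w) == length(conv_kernels),
            length(fc_sizes) >= 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernels = conv_kernels, conv_strides = conv_strides,
                 conv_pad_w = as.integer(conv_pad_w),
                 levels = as.integer(levels),
                 fc_sizes = as.integer(fc_sizes),
                 lr = lr, momentum = momentum, epochs = as.integer(epochs),
                 batch = as.integer(batch), seed = as.integer(seed)),
            class = "spp_config")
}

#' Fixed pyramid output length
#'
#' `sum(levels^2) * channels`, the length of the [spp_pool()] vector
#' independent of the input's spatial size (4,200 for the default
#' levels `[4, 2, 1]` with 200 channels).
#'
#' @param levels integer vector of pyramid levels.
#' @param channels channel count of the pooled feature map.
#' @return integer scalar.
#' @export
spp_output_length <- function(levels, channels) sum(levels^2) * channels

# ---- im2col convolution -------------------------------------------------

# gather-index array for patches of a (H, W, C) array; cached per shape
.conv_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, C, kh, kw, sh, sw) {
  key <- paste(H, W, C, kh, kw, sh, sw, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H - kh) %/% sh + 1L
  Wo <- (W - kw) %/% sw + 1L
  ind <- array(0L, c(kh * kw * C, Ho * Wo))
  p <- 0L
  patch <- integer(kh * kw * C)
  q <- 0L
  for (ch in seq_len(C)) for (c0 in seq_len(kw)) for (r0 in seq_len(kh)) {
    q <- q + 1L
    patch[q] <- r0 + (c0 - 1L) * H + (ch - 1L) * H * W
  }
  offs <- integer(Ho * Wo)
  for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
    p <- p + 1L
    offs[p] <- (i - 1L) * sh + ((j - 1L) * sw) * H
  }
  ind <- outer(patch - 1L, offs, "+") + 1L
  out <- list(ind = ind, Ho = Ho, Wo = Wo)
  .conv_cache[[key]] <- out
  out
}

pad_width <- function(x, pad) {
  if (pad <= 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + pad, d[3]))
  out[, seq_len(d[2]), ] <- x
  out
}

#' Strided 2D convolution (cross-correlation) forward pass
#'
#' Valid convolution in the height dimension; the width can be zero-padded
#' on the right (`pad_w`) to preserve width. Input height 610 with kernel
#' height 10 and stride 5 gives output height 121; input width 21 with
#' kernel width 4 and stride 1 gives 18.
#'
#' @param x numeric array `(H, W, C_in)` (a matrix is treated as C_in = 1).
#' @param weights array `(kh, kw, C_in, C_out)`.
#' @param bias numeric vector of length `C_out`.
#' @param stride `c(height, width)` strides.
#' @param pad_w right zero-padding in the width dimension.
#' @return array `(H_out, W_out, C_out)`.
#' @export
conv_forward <- function(x, weights, bias = NULL, stride = c(1L, 1L),
                         pad_w = 0L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  x <- pad_width(x, pad_w)
  d <- dim(x); wd <- dim(weights)
  if (wd[3] != d[3]) stop("channel mismatch", call. = FALSE)
  if (wd[1] > d[1] || wd[2] > d[2])
    stop("kernel larger than input", call. = FALSE)
  ci <- conv_indices(d[1], d[2], d[3], wd[1], wd[2], stride[1], stride[2])
  Xcol <- matrix(x[ci$ind], nrow = nrow(ci$ind))     # (kh*kw*Cin) x (Ho*Wo)
  Wmat <- matrix(weights, nrow = wd[1] * wd[2] * wd[3])
  out <- crossprod(Xcol, Wmat)                        # (Ho*Wo) x Cout
  if (!is.null(bias)) out <- sweep(out, 2, bias, "+")
  array(out, c(ci$Ho, ci$Wo, wd[4]))
}

# forward keeping the column matrix for backprop
conv_fwd_full <- function(x, weights, bias, stride, pad_w) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  xp <- pad_width(x, pad_w)
  d <- dim(xp); wd <- dim(weights)
  ci <- conv_indices(d[1], d[2], d[3], wd[1], wd[2], stride[1], stride[2])
  Xcol <- matrix(xp[ci$ind], nrow = nrow(ci$ind))
  Wmat <- matrix(weights, nrow = wd[1] * wd[2] * wd[3])
  pre <- sweep(crossprod(Xcol, Wmat), 2, bias, "+")
  list(out = array(pmax(pre, 0), c(ci$Ho, ci$Wo, wd[4])),
       mask = pre > 0, Xcol = Xcol, ci = ci, dim_in = d, pad_w = pad_w)
}

conv_bwd <- function(fwd, weights, d_out_mat, need_dx = TRUE) {
  # d_out_mat: (Ho*Wo) x Cout, already multiplied by the ReLU mask
  wd <- dim(weights)
  dW <- array(fwd$Xcol %*% d_out_mat, wd)
  db <- colSums(d_out_mat)
  dX <- NULL
  if (need_dx) {
    Wmat <- matrix(weights, nrow = wd[1] * wd[2] * wd[3])
    dXcol <- Wmat %*% t(d_out_mat)                   # (khkwC) x (HoWo)
    acc <- rowsum(as.vector(dXcol), as.vector(fwd$ci$ind))
    dxv <- numeric(prod(fwd$dim_in))
    dxv[as.integer(rownames(acc))] <- acc
    dX <- array(dxv, fwd$dim_in)
    if (fwd$pad_w > 0L)
      dX <- dX[, seq_len(fwd$dim_in[2] - fwd$pad_w), , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# ---- spatial pyramid pooling --------------------------------------------

spp_windows <- function(a, n) {
  win <- ceiling(a / n); str <- floor(a / n)
  starts <- (seq_len(n) - 1L) * str + 1L
  ends <- pmin(starts + win - 1L, a)
  cbind(starts, ends)
}

#' Spatial pyramid pooling
#'
#' Max-pools an `(H, W, C)` feature map at each pyramid level `n` with
#' per-dimension sliding windows of size `ceiling(a/n)` and stride
#' `floor(a/n)` (`a` the spatial extent), yielding `n x n x C` maxima per
#' level; levels are concatenated into a vector of fixed length
#' `sum(n^2) * C` regardless of `H` and `W`.
#'
#' @param x numeric array `(H, W, C)` (a matrix is treated as one channel).
#' @param levels integer vector of pyramid levels.
#' @return numeric vector of length `sum(levels^2) * C`.
#' @export
spp_pool <- function(x, levels) {
  spp_pool_full(x, levels)$out
}

spp_pool_full <- function(x, levels) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (any(levels > H) || any(levels > W))
    stop("pyramid level exceeds a spatial dimension", call. = FALSE)
  pieces <- list(); args <- list()
  for (n in levels) {
    wr <- spp_windows(H, n); wc <- spp_windows(W, n)
    vals <- array(0, c(n, n, C)); amax <- array(0L, c(n, n, C))
    for (j in seq_len(n)) for (i in seq_len(n)) {
      rows <- wr[i, 1]:wr[i, 2]; cols <- wc[j, 1]:wc[j, 2]
      sub <- x[rows, cols, , drop = FALSE]
      m2 <- matrix(sub, ncol = C)                    # (win area) x C
      arg <- max.col(t(m2), ties.method = "first")   # per-channel argmax
      vals[i, j, ] <- m2[cbind(arg, seq_len(C))]
      # convert window-local argmax to linear index in x
      wh <- length(rows)
      r_loc <- (arg - 1L) %% wh + 1L
      c_loc <- (arg - 1L) %/% wh + 1L
      amax[i, j, ] <- rows[r_loc] + (cols[c_loc] - 1L) * H +
        (seq_len(C) - 1L) * H * W
    }
    pieces[[length(pieces) + 1L]] <- as.vector(vals)
    args[[length(args) + 1L]] <- as.vector(amax)
  }
  list(out = unlist(pieces), argmax = unlist(args), dim_in = d)
}

spp_bwd <- function(full, d_out) {
  acc <- rowsum(d_out, full$argmax)
  dxv <- numeric(prod(full$dim_in))
  dxv[as.integer(rownames(acc))] <- acc
  array(dxv, full$dim_in)
}

# ---- model --------------------------------------------------------------

init_weights <- function(config) {
  kern <- config$conv_kernels
  ch <- c(1L, config$conv_channels)
  w <- list(conv = list(), fc = list())
  for (l in seq_along(kern)) {
    fan_in <- kern[[l]][1] * kern[[l]][2] * ch[l]
    w$conv[[l]] <- list(
      W = array(stats::rnorm(fan_in * ch[l + 1], sd = sqrt(2 / fan_in)),
                c(kern[[l]][1], kern[[l]][2], ch[l], ch[l + 1])),
      b = numeric(ch[l + 1]))
  }
  in_len <- spp_output_length(config$levels, utils::tail(config$conv_channels, 1))
  sizes <- c(in_len, config$fc_sizes)
  nfc <- length(sizes) - 1L
  for (l in seq_len(nfc)) {
    # zero-init the output layer: the net starts at the uniform predictive
    # distribution, which keeps early updates well-scaled
    sd_l <- if (l == nfc) 0 else sqrt(2 / sizes[l])
    w$fc[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd_l),
                 nrow = sizes[l]),
      b = numeric(sizes[l + 1]))
  }
  w
}

grad_norm <- function(g) {
  s <- 0
  for (l in seq_along(g$conv))
    s <- s + sum(g$conv[[l]]$dW^2) + sum(g$conv[[l]]$db^2)
  for (l in seq_along(g$fc))
    s <- s + sum(g$fc[[l]]$dW^2) + sum(g$fc[[l]]$db^2)
  sqrt(s)
}

scale_grads <- function(g, f) {
  for (l in seq_along(g$conv)) {
    g$conv[[l]]$dW <- g$conv[[l]]$dW * f
    g$conv[[l]]$db <- g$conv[[l]]$db * f
  }
  for (l in seq_along(g$fc)) {
    g$fc[[l]]$dW <- g$fc[[l]]$dW * f
    g$fc[[l]]$db <- g$fc[[l]]$db * f
  }
  g
}

# minimum input height for the conv stack to reach max(levels) rows
min_input_height <- function(config) {
  h <- max(config$levels)
  for (l in rev(seq_along(config$conv_kernels))) {
    h <- (h - 1L) * config$conv_strides[[l]][1] + config$conv_kernels[[l]][1]
  }
  h
}

as_map_matrix <- function(m) {
  if (inherits(m, "feature_map")) m$matrix else as.matrix(m)
}

prep_input <- function(mat, normalization, min_h) {
  z <- sweep(sweep(mat, 2, normalization$mean), 2, normalization$sd, "/")
  z[!is.finite(z)] <- 0
  if (nrow(z) < min_h) {                 # zero-pad short maps
    z <- rbind(z, matrix(0, min_h - nrow(z), ncol(z)))
  }
  array(z, c(dim(z), 1L))
}

net_forward <- function(x, w, config, keep = FALSE) {
  fwd_conv <- vector("list", length(w$conv))
  cur <- x
  for (l in seq_along(w$conv)) {
    f <- conv_fwd_full(cur, w$conv[[l]]$W, w$conv[[l]]$b,
                       config$conv_strides[[l]], config$conv_pad_w[l])
    fwd_conv[[l]] <- f
    cur <- f$out
  }
  sp <- spp_pool_full(cur, config$levels)
  v <- sp$out
  nfc <- length(w$fc)
  acts <- vector("list", nfc)
  for (l in seq_len(nfc)) {
    z <- drop(crossprod(w$fc[[l]]$W, v)) + w$fc[[l]]$b
    if (l < nfc) {
      zr <- pmax(z, 0)
      acts[[l]] <- list(input = v, pre = z, out = zr)
      v <- zr
    } else {
      acts[[l]] <- list(input = v, pre = z)
    }
  }
  z <- acts[[nfc]]$pre
  p <- exp(z - max(z)); p <- p / sum(p)
  out <- list(prob = p)
  if (keep) { out$conv <- fwd_conv; out$spp <- sp; out$fc <- acts }
  out
}

net_backward <- function(fw, w, config, y_onehot) {
  nfc <- length(w$fc)
  grads <- list(conv = vector("list", length(w$conv)),
                fc = vector("list", nfc))
  delta <- fw$prob - y_onehot                # softmax + CE
  for (l in rev(seq_len(nfc))) {
    a <- fw$fc[[l]]
    grads$fc[[l]] <- list(dW = outer(a$input, delta), db = delta)
    delta <- drop(w$fc[[l]]$W %*% delta)
    if (l > 1L) delta <- delta * (fw$fc[[l - 1L]]$pre > 0)
  }
  # delta is now the gradient at the SPP output
  d_conv_out <- spp_bwd(fw$spp, delta)
  for (l in rev(seq_along(w$conv))) {
    f <- fw$conv[[l]]
    dmat <- matrix(d_conv_out, ncol = dim(w$conv[[l]]$W)[4]) * f$mask
    bk <- conv_bwd(f, w$conv[[l]]$W, dmat, need_dx = l > 1L)
    grads$conv[[l]] <- bk[c("dW", "db")]
    if (l > 1L) d_conv_out <- bk$dX
  }
  grads
}

#' Train the SPP-net classifier
#'
#' Momentum SGD on softmax cross-entropy over variable-height feature
#' maps. Column normalization statistics are computed from the training
#' maps (stacked rows) and stored in the model; maps shorter than the
#' minimum height the conv stack requires are zero-padded. Deterministic
#' under a fixed config seed.
#'
#' @param dataset list of elements `list(map = , label = )` where `map` is
#'   a [build_feature_map()] object or a plain `n x 21` matrix and `label`
#'   a class value (two or more classes must be present).
#' @param config an [spp_config()].
#' @param verbose print per-epoch loss.
#' @return object of class `spp_model` with weights, normalization
#'   statistics, class levels, and the training loss log.
#' @export
spp_train <- function(dataset, config = spp_config(), verbose = FALSE) {
  if (length(dataset) < 2L) stop("dataset too small", call. = FALSE)
  labels <- vapply(dataset, function(d) as.character(d$label), character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("dataset must contain at least two classes", call. = FALSE)
  if (length(classes) != utils::tail(config$fc_sizes, 1))
    stop("last fc size must equal the number of classes", call. = FALSE)
  y <- match(labels, classes)
  mats <- lapply(dataset, function(d) as_map_matrix(d$map))
  stacked <- do.call(rbind, mats)
  mu <- colMeans(stacked); sdv <- apply(stacked, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1; mu[!is.finite(mu)] <- 0
  normalization <- list(mean = mu, sd = sdv)
  min_h <- min_input_height(config)
  xs <- lapply(mats, prep_input, normalization = normalization, min_h = min_h)

  n <- length(xs)
  loss_log <- numeric(config$epochs)
  w <- NULL
  withr_seed(config$seed, {
    w <- init_weights(config)
    vel <- rapply(w, function(z) z * 0, how = "replace")
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1L, n)]
        gacc <- NULL
        for (i in idx) {
          fw <- net_forward(xs[[i]], w, config, keep = TRUE)
          onehot <- as.numeric(seq_along(classes) == y[i])
          ep_loss <- ep_loss - log(max(fw$prob[y[i]], 1e-12))
          g <- net_backward(fw, w, config, onehot)
          gacc <- if (is.null(gacc)) g else add_grads(gacc, g)
        }
        # clip the batch-mean gradient norm at 5 to keep momentum SGD
        # stable against the heavy-tailed pooled maxima
        nrm <- grad_norm(gacc) / length(idx)
        if (nrm > 5) gacc <- scale_grads(gacc, 5 / nrm)
        scale <- config$lr / length(idx)
        for (l in seq_along(w$conv)) {
          vel$conv[[l]]$W <- config$momentum * vel$conv[[l]]$W -
            scale * gacc$conv[[l]]$dW
          vel$conv[[l]]$b <- config$momentum * vel$conv[[l]]$b -
            scale * gacc$conv[[l]]$db
          w$conv[[l]]$W <- w$conv[[l]]$W + vel$conv[[l]]$W
          w$conv[[l]]$b <- w$conv[[l]]$b + vel$conv[[l]]$b
        }
        for (l in seq_along(w$fc)) {
          vel$fc[[l]]$W <- config$momentum * vel$fc[[l]]$W -
            scale * gacc$fc[[l]]$dW
          vel$fc[[l]]$b <- config$momentum * vel$fc[[l]]$b -
            scale * gacc$fc[[l]]$db
          w$fc[[l]]$W <- w$fc[[l]]$W + vel$fc[[l]]$W
          w$fc[[l]]$b <- w$fc[[l]]$b + vel$fc[[l]]$b
        }
      }
      loss_log[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, loss_log[ep]))
    }
  })
  structure(list(config = config, weights = w, normalization = normalization,
                 classes = classes, loss_log = loss_log),
            class = "spp_model")
}

add_grads <- function(a, b) {
  for (l in seq_along(a$conv)) {
    a$conv[[l]]$dW <- a$conv[[l]]$dW + b$conv[[l]]$dW
    a$conv[[l]]$db <- a$conv[[l]]$db + b$conv[[l]]$db
  }
  for (l in seq_along(a$fc)) {
    a$fc[[l]]$dW <- a$fc[[l]]$dW + b$fc[[l]]$dW
    a$fc[[l]]$db <- a$fc[[l]]$db + b$fc[[l]]$db
  }
  a
}

#' @export
print.spp_model <- function(x, ...) {
  cat(sprintf("<spp_model> classes: %s; final loss %.4f\n",
              paste(x$classes, collapse = "/"),
              utils::tail(x$loss_log, 1)))
  invisible(x)
}

#' Predict with a trained SPP model
#'
#' @param object an `spp_model`.
#' @param maps list of feature maps (or a single map).
#' @param ... unused.
#' @return data.frame with predicted `class` and per-class probabilities.
#' @export
predict.spp_model <- function(object, maps, ...) {
  if (inherits(maps, "feature_map") || is.matrix(maps)) maps <- list(maps)
  min_h <- min_input_height(object$config)
  probs <- t(vapply(maps, function(m) {
    x <- prep_input(as_map_matrix(m), object$normalization, min_h)
    net_forward(x, object$weights, object$config)$prob
  }, numeric(length(object$classes))))
  colnames(probs) <- object$classes
  data.frame(class = object$classes[max.col(probs, ties.method = "first")],
             probs, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn nonnegative counts with a positive total.
#' @return numeric in `[0, 1]`.
#' @export
accuracy_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("accuracy undefined for zero total", call. = FALSE)
  (tp + tn) / tot
}

# Stratified fold assignment. Within each class, trials are dealt
# round-robin after a seeded shuffle; the starting fold advances across
# classes so the leftover trials land on distinct folds and overall fold
# sizes differ by at most one.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

#' k-fold cross-validated accuracy
#'
#' Stratified folds as equal as possible; every trial is tested exactly
#' once. A fresh model is trained on each training split.
#'
#' @inheritParams spp_train
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed (training seeds derive from the
#'   config seed plus the fold index).
#' @return list with `fold_accuracy` (length `k`), `mean_accuracy`, and
#'   the fold assignment.
#' @export
cross_validate <- function(dataset, config = spp_config(), k = 5L,
                           seed = 1L) {
  n <- length(dataset)
  if (k < 2L || k > n) stop("k must lie in [2, n]", call. = FALSE)
  labels <- vapply(dataset, function(d) as.character(d$label), character(1))
  fold <- stratified_folds(labels, k, seed)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- dataset[fold != f]; te <- dataset[fold == f]
    cfg <- config; cfg$seed <- config$seed + f
    model <- spp_train(tr, cfg)
    pred <- predict(model, lapply(te, `[[`, "map"))
    accs[f] <- mean(pred$class == vapply(te, function(d)
      as.character(d$label), character(1)))
  }
  list(fold_accuracy = accs, mean_accuracy = mean(accs), fold = fold)
}

#' Serialize / restore a trained model as JSON
#'
#' Round-trips the configuration, weights, normalization statistics and
#' class levels; restored models produce the same predictions.
#'
#' @param model an `spp_model`.
#' @param path file path.
#' @return `read_spp_model` returns the model; `write_spp_model` the path,
#'   invisibly.
#' @export
write_spp_model <- function(model, path) {
  stopifnot(inherits(model, "spp_model"))
  ser <- list(
    config = unclass(model$config),
    conv = lapply(model$weights$conv, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
    fc = lapply(model$weights$fc, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
    normalization = model$normalization,
    classes = model$classes, loss_log = model$loss_log)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spp_model
#' @export
read_spp_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  cfg <- s$config
  fix_pairs <- function(p) {
    if (is.matrix(p)) lapply(seq_len(nrow(p)), function(i) as.integer(p[i, ]))
    else lapply(p, as.integer)
  }
  cfg$conv_kernels <- fix_pairs(cfg$conv_kernels)
  cfg$conv_strides <- fix_pairs(cfg$conv_strides)
  class(cfg) <- "spp_config"
  w <- list(
    conv = lapply(s$conv, function(l)
      list(W = array(unlist(l$W), unlist(l$dim)), b = unlist(l$b))),
    fc = lapply(s$fc, function(l)
      list(W = array(unlist(l$W), unlist(l$dim)), b = unlist(l$b))))
  structure(list(config = cfg, weights = w,
                 normalization = list(mean = unlist(s$normalization$mean),
                                      sd = unlist(s$normalization$sd)),
                 classes = s$classes, loss_log = s$loss_log),
            class = "spp_model")
}
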