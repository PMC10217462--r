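# 3D convolutional autoencoder: three conv(3x3x3) + LeakyReLU + maxpool(2)
# encoder stages, mirrored decoder with nearest-neighbour upsampling, final
# sigmoid; binary cross-entropy loss minimized with Adam. The flattened
# activations after the third pooling stage are the deep-feature vector.

.lrelu <- function(x, a) ifelse(x > 0, x, a * x)
.lrelu_grad <- function(x, a) ifelse(x > 0, 1, a)

#' Autoencoder architecture specification
#'
#' @param input_grid integer(3) voxel grid, each divisible by 8.
#' @param channels widths of the first two encoder stages (decoder
#'   mirrored). Default \code{c(16, 8)}.
#' @param bottleneck_channels channels of the third (bottleneck) stage.
#'   With the reference grid 224 x 224 x 160 and 1 bottleneck channel the
#'   flattened bottleneck has 28 * 28 * 20 = 15,680 units.
#' @param alpha LeakyReLU negative slope.
#' @return an \code{AutoencoderSpec} list with the derived
#'   \code{bottleneck_len}.
#' @export
autoencoderSpec <- function(input_grid = c(224L, 224L, 160L),
                            channels = c(16L, 8L),
                            bottleneck_channels = 1L, alpha = 0.1) {
  input_grid <- as.integer(input_grid)
  if (length(input_grid) != 3L || any(input_grid %% 8L != 0L))
    stop("input_grid must be three dims, each divisible by 8")
  stopifnot(length(channels) == 2L, bottleneck_channels >= 1L)
  structure(list(input_grid = input_grid,
                 channels = as.integer(channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 alpha = alpha,
                 bottleneck_len = as.integer(prod(input_grid %/% 8L)) *
                   as.integer(bottleneck_channels)),
            class = "AutoencoderSpec")
}

#' Training configuration for the autoencoder / CNN
#' @param epochs,lr,batch,seed training schedule; Adam optimizer.
#' @return a \code{TrainingConfig} list.
#' @export
trainingConfig <- function(epochs = 50L, lr = 1e-3, batch = 2L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch = as.integer(batch), seed = as.integer(seed)),
            class = "TrainingConfig")
}

.he_init <- function(dims, fanin) {
  array(rnorm(prod(dims), sd = sqrt(2 / fanin)), dims)
}

#' Build a 3D autoencoder
#' @param spec \code{\link{autoencoderSpec}}.
#' @param seed seed fixing the initial weights.
#' @return an \code{Autoencoder3D} model (weights + spec).
#' @export
buildAutoencoder <- function(spec = autoencoderSpec(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c1 <- spec$channels[1]; c2 <- spec$channels[2]
  cb <- spec$bottleneck_channels
  W <- list(
    e1 = list(w = .he_init(c(3, 3, 3, 1, c1), 27), b = numeric(c1)),
    e2 = list(w = .he_init(c(3, 3, 3, c1, c2), 27 * c1), b = numeric(c2)),
    e3 = list(w = .he_init(c(3, 3, 3, c2, cb), 27 * c2), b = numeric(cb)),
    d1 = list(w = .he_init(c(3, 3, 3, cb, c2), 27 * cb), b = numeric(c2)),
    d2 = list(w = .he_init(c(3, 3, 3, c2, c1), 27 * c2), b = numeric(c1)),
    d3 = list(w = .he_init(c(3, 3, 3, c1, 1), 27 * c1), b = numeric(1)))
  structure(list(spec = spec, W = W, seed = as.integer(seed)),
            class = "Autoencoder3D")
}

.as_chan_array <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

.conv_stage_fwd <- function(x, layer, alpha, pool = TRUE) {
  d <- dim(x)
  z <- cpp_conv3_fwd(x, d[1:3], layer$w, d[4], length(layer$b), layer$b)
  h <- .lrelu(z, alpha); dim(h) <- dim(z)
  if (!pool) return(list(x = x, z = z, h = h))
  p <- cpp_maxpool_fwd(h, dim(h)[1:3], dim(h)[4])
  list(x = x, z = z, h = h, p = p$y, argmax = p$argmax)
}

# memory-lean encoder-only pass (activations freed stage by stage, LeakyReLU
# applied in place) -- used for feature extraction on large grids
.ae_encode <- function(model, x) {
  a <- model$spec$alpha
  cur <- x
  for (nm in c("e1", "e2", "e3")) {
    d <- dim(cur)
    layer <- model$W[[nm]]
    z <- cpp_conv3_fwd(cur, d[1:3], layer$w, d[4], length(layer$b), layer$b)
    rm(cur)
    neg <- z < 0
    z[neg] <- a * z[neg]
    rm(neg)
    p <- cpp_maxpool_fwd(z, dim(z)[1:3], dim(z)[4])
    rm(z)
    cur <- p$y
  }
  cur
}

# full forward pass; cache activations when training
.ae_forward <- function(model, vol, cache = FALSE, encoder_only = FALSE) {
  a <- model$spec$alpha
  x <- .as_chan_array(vol)
  if (encoder_only)
    return(list(bottleneck = .ae_encode(model, x)))
  s1 <- .conv_stage_fwd(x, model$W$e1, a)
  s2 <- .conv_stage_fwd(s1$p, model$W$e2, a)
  s3 <- .conv_stage_fwd(s2$p, model$W$e3, a)
  bottleneck <- s3$p
  u1 <- cpp_upsample_fwd(bottleneck, dim(bottleneck)[1:3], dim(bottleneck)[4])
  t1 <- .conv_stage_fwd(u1, model$W$d1, a, pool = FALSE)
  u2 <- cpp_upsample_fwd(t1$h, dim(t1$h)[1:3], dim(t1$h)[4])
  t2 <- .conv_stage_fwd(u2, model$W$d2, a, pool = FALSE)
  u3 <- cpp_upsample_fwd(t2$h, dim(t2$h)[1:3], dim(t2$h)[4])
  d3 <- dim(u3)
  z <- cpp_conv3_fwd(u3, d3[1:3], model$W$d3$w, d3[4], 1L, model$W$d3$b)
  yhat <- 1 / (1 + exp(-z)); dim(yhat) <- dim(z)
  res <- list(yhat = yhat, bottleneck = bottleneck)
  if (cache)
    res <- c(res, list(s1 = s1, s2 = s2, s3 = s3, u1 = u1, t1 = t1,
                       u2 = u2, t2 = t2, u3 = u3, z = z))
  res
}

.stage_bwd <- function(stage, layer, gh, alpha, gpool = NULL) {
  # gh: gradient wrt stage output h (or pooled output via gpool + argmax)
  if (!is.null(gpool)) {
    gh <- cpp_maxpool_bwd(stage$argmax, gpool, dim(stage$h)[1:3],
                          dim(stage$h)[4])
  }
  gz <- gh * .lrelu_grad(stage$z, alpha)
  dim(gz) <- dim(stage$z)
  d <- dim(stage$x)
  g <- cpp_conv3_bwd(stage$x, d[1:3], layer$w, d[4], length(layer$b), gz)
  g
}

# gradients of mean BCE wrt all weights for one volume
.ae_backward <- function(model, vol, fw) {
  a <- model$spec$alpha
  x <- .as_chan_array(vol)
  n <- length(x)
  gz <- (fw$yhat - x) / n
  dim(gz) <- dim(fw$z)
  d3 <- dim(fw$u3)
  gd3 <- cpp_conv3_bwd(fw$u3, d3[1:3], model$W$d3$w, d3[4], 1L, gz)
  gt2h <- cpp_upsample_bwd(gd3$gx, d3[1:3], d3[4])
  gd2 <- .stage_bwd(fw$t2, model$W$d2, gt2h, a)
  gt1h <- cpp_upsample_bwd(gd2$gx, dim(fw$u2)[1:3], dim(fw$u2)[4])
  gd1 <- .stage_bwd(fw$t1, model$W$d1, gt1h, a)
  gbn <- cpp_upsample_bwd(gd1$gx, dim(fw$u1)[1:3], dim(fw$u1)[4])
  ge3 <- .stage_bwd(fw$s3, model$W$e3, NULL, a, gpool = gbn)
  ge2 <- .stage_bwd(fw$s2, model$W$e2, NULL, a, gpool = ge3$gx)
  ge1 <- .stage_bwd(fw$s1, model$W$e1, NULL, a, gpool = ge2$gx)
  list(e1 = ge1, e2 = ge2, e3 = ge3, d1 = gd1, d2 = gd2,
       d3 = list(gw = gd3$gw, gb = gd3$gb))
}

.bce <- function(yhat, x) {
  eps <- 1e-7
  y <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(x * log(y) + (1 - x) * log(1 - y))
}

.adam_state <- function(W) {
  lapply(W, function(l) list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
                             mb = numeric(length(l$b)),
                             vb = numeric(length(l$b))))
}

.adam_step <- function(W, G, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(W)) {
    gw <- array(G[[nm]]$gw, dim(W[[nm]]$w)); gb <- G[[nm]]$gb
    st[[nm]]$mw <- beta1 * st[[nm]]$mw + (1 - beta1) * gw
    st[[nm]]$vw <- beta2 * st[[nm]]$vw + (1 - beta2) * gw^2
    st[[nm]]$mb <- beta1 * st[[nm]]$mb + (1 - beta1) * gb
    st[[nm]]$vb <- beta2 * st[[nm]]$vb + (1 - beta2) * gb^2
    mh <- st[[nm]]$mw / (1 - beta1^t); vh <- st[[nm]]$vw / (1 - beta2^t)
    W[[nm]]$w <- W[[nm]]$w - lr * mh / (sqrt(vh) + eps)
    mhb <- st[[nm]]$mb / (1 - beta1^t); vhb <- st[[nm]]$vb / (1 - beta2^t)
    W[[nm]]$b <- W[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
  }
  list(W = W, st = st)
}

#' Train the autoencoder
#'
#' Minimizes mean binary cross-entropy between the input volumes (values in
#' [0,1]) and their reconstructions with Adam. The seed fixes batch order;
#' the loss trace holds the mean training BCE per epoch.
#'
#' @param model \code{\link{buildAutoencoder}} result.
#' @param volumes list of \linkS4class{RadVolume}s (or 3D arrays) matching
#'   the spec grid, values in [0,1].
#' @param config \code{\link{trainingConfig}}.
#' @return the trained model, with \code{$loss_trace}.
#' @export
trainAutoencoder <- function(model, volumes, config = trainingConfig()) {
  vols <- lapply(volumes, function(v) if (is(v, "RadVolume")) v@data else v)
  if (!length(vols)) stop("no training volumes")
  for (v in vols) {
    if (!identical(dim(v), as.integer(model$spec$input_grid)) &&
        !identical(as.integer(dim(v)), model$spec$input_grid))
      stop("volume grid does not match the autoencoder spec")
    if (min(v) < 0 || max(v) > 1)
      stop("autoencoder inputs must lie in [0,1] (BCE loss)")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  st <- .adam_state(model$W)
  trace <- numeric(config$epochs)
  t <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(vols))
    losses <- numeric(length(vols))
    bstart <- seq(1, length(ord), by = config$batch)
    for (b in bstart) {
      ids <- ord[b:min(b + config$batch - 1, length(ord))]
      G <- NULL
      for (i in ids) {
        fw <- .ae_forward(model, vols[[i]], cache = TRUE)
        losses[i] <- .bce(fw$yhat, .as_chan_array(vols[[i]]))
        g <- .ae_backward(model, vols[[i]], fw)
        if (is.null(G)) G <- g
        else for (nm in names(G)) {
          G[[nm]]$gw <- G[[nm]]$gw + g[[nm]]$gw
          G[[nm]]$gb <- G[[nm]]$gb + g[[nm]]$gb
        }
      }
      for (nm in names(G)) {
        G[[nm]]$gw <- G[[nm]]$gw / length(ids)
        G[[nm]]$gb <- G[[nm]]$gb / length(ids)
      }
      t <- t + 1
      up <- .adam_step(model$W, G, st, config$lr, t)
      model$W <- up$W; st <- up$st
    }
    trace[ep] <- mean(losses)
  }
  model$loss_trace <- trace
  model
}

#' Extract the flattened bottleneck deep-feature vector
#'
#' Inference-mode encoder pass; deterministic for a fixed model.
#'
#' @param model trained (or built) \code{Autoencoder3D}.
#' @param vol \linkS4class{RadVolume} or 3D array on the spec grid.
#' @param flavour optional flavour name attached as an attribute.
#' @return numeric vector of length \code{spec$bottleneck_len}.
#' @export
extractBottleneck <- function(model, vol, flavour = NULL) {
  x <- if (is(vol, "RadVolume")) vol@data else vol
  if (!identical(as.integer(dim(x)), model$spec$input_grid))
    stop("volume grid does not match the autoencoder spec")
  fw <- .ae_forward(model, x, encoder_only = TRUE)
  v <- as.numeric(fw$bottleneck)
  stopifnot(length(v) == model$spec$bottleneck_len)
  if (!is.null(flavour)) attr(v, "flavour") <- flavour
  v
}

#' Reconstruct a volume through the autoencoder (for diagnostics/tests)
#' @param model \code{Autoencoder3D}.
#' @param vol input volume or array on the spec grid.
#' @return array of reconstructed values in (0,1), same grid.
#' @export
reconstructVolume <- function(model, vol) {
  x <- if (is(vol, "RadVolume")) vol@data else vol
  fw <- .ae_forward(model, x)
  y <- fw$yhat
  dim(y) <- dim(.as_chan_array(x))
  array(y, dim(x))
}
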