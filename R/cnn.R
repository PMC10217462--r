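# End-to-end 3D CNN baseline: the encoder stack (3 x conv/LeakyReLU/pool)
# followed by global average pooling and a dense sigmoid output, trained
# with BCE + Adam on the binary outcome.

#' Build the 3D CNN classifier
#'
#' @param input_grid integer(3), divisible by 8.
#' @param channels widths of the three conv stages. Default c(16, 8, 4);
#'   narrow widths keep desk-scale runs cheap.
#' @param alpha LeakyReLU slope.
#' @param seed weight-init seed.
#' @return a \code{CNN3D} model.
#' @export
buildCNN <- function(input_grid, channels = c(16L, 8L, 4L), alpha = 0.1,
                     seed = 1L) {
  input_grid <- as.integer(input_grid)
  if (any(input_grid %% 8L != 0L)) stop("input_grid must be divisible by 8")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  W <- list(
    e1 = list(w = .he_init(c(3, 3, 3, 1, c1), 27), b = numeric(c1)),
    e2 = list(w = .he_init(c(3, 3, 3, c1, c2), 27 * c1), b = numeric(c2)),
    e3 = list(w = .he_init(c(3, 3, 3, c2, c3), 27 * c2), b = numeric(c3)))
  dense <- list(w = rnorm(c3, sd = sqrt(1 / c3)), b = 0)
  structure(list(input_grid = input_grid, channels = as.integer(channels),
                 alpha = alpha, W = W, dense = dense,
                 seed = as.integer(seed)),
            class = "CNN3D")
}

.cnn_forward <- function(model, vol, cache = FALSE) {
  a <- model$alpha
  x <- .as_chan_array(if (is(vol, "RadVolume")) vol@data else vol)
  s1 <- .conv_stage_fwd(x, model$W$e1, a)
  s2 <- .conv_stage_fwd(s1$p, model$W$e2, a)
  s3 <- .conv_stage_fwd(s2$p, model$W$e3, a)
  d <- dim(s3$p)
  nsp <- prod(d[1:3])
  g <- colMeans(matrix(s3$p, nsp, d[4]))  # global average pool
  z <- sum(model$dense$w * g) + model$dense$b
  p <- 1 / (1 + exp(-z))
  res <- list(p = p, g = g)
  if (cache) res <- c(res, list(s1 = s1, s2 = s2, s3 = s3, d = d, nsp = nsp))
  res
}

.cnn_backward <- function(model, fw, y) {
  a <- model$alpha
  dz <- fw$p - y
  gdw <- dz * fw$g
  gdb <- dz
  gg <- dz * model$dense$w
  gp3 <- array(rep(gg / fw$nsp, each = fw$nsp), fw$d)
  ge3 <- .stage_bwd(fw$s3, model$W$e3, NULL, a, gpool = gp3)
  ge2 <- .stage_bwd(fw$s2, model$W$e2, NULL, a, gpool = ge3$gx)
  ge1 <- .stage_bwd(fw$s1, model$W$e1, NULL, a, gpool = ge2$gx)
  list(W = list(e1 = ge1, e2 = ge2, e3 = ge3),
       dense = list(gw = gdw, gb = gdb))
}

#' Train the CNN classifier
#'
#' @param model \code{\link{buildCNN}} result.
#' @param volumes list of volumes/arrays in [0,1] on the model grid.
#' @param labels binary 0/1 vector.
#' @param config \code{\link{trainingConfig}}.
#' @param checkpoint_epochs optional epochs at which to snapshot the model
#'   (for checkpoint ensembling); snapshots returned in
#'   \code{$checkpoints}.
#' @return trained model with \code{$loss_trace} (mean BCE per epoch).
#' @export
trainCNN <- function(model, volumes, labels, config = trainingConfig(),
                     checkpoint_epochs = integer(0)) {
  stopifnot(length(volumes) == length(labels), all(labels %in% c(0, 1)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  st <- .adam_state(model$W)
  std <- list(mw = numeric(length(model$dense$w)),
              vw = numeric(length(model$dense$w)), mb = 0, vb = 0)
  trace <- numeric(config$epochs)
  checkpoints <- list()
  t <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(volumes))
    losses <- numeric(length(volumes))
    for (b in seq(1, length(ord), by = config$batch)) {
      ids <- ord[b:min(b + config$batch - 1, length(ord))]
      G <- NULL; gd <- NULL
      for (i in ids) {
        fw <- .cnn_forward(model, volumes[[i]], cache = TRUE)
        eps <- 1e-7
        p <- min(max(fw$p, eps), 1 - eps)
        losses[i] <- -(labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
        g <- .cnn_backward(model, fw, labels[i])
        if (is.null(G)) { G <- g$W; gd <- g$dense }
        else {
          for (nm in names(G)) {
            G[[nm]]$gw <- G[[nm]]$gw + g$W[[nm]]$gw
            G[[nm]]$gb <- G[[nm]]$gb + g$W[[nm]]$gb
          }
          gd$gw <- gd$gw + g$dense$gw; gd$gb <- gd$gb + g$dense$gb
        }
      }
      for (nm in names(G)) {
        G[[nm]]$gw <- G[[nm]]$gw / length(ids)
        G[[nm]]$gb <- G[[nm]]$gb / length(ids)
      }
      gd$gw <- gd$gw / length(ids); gd$gb <- gd$gb / length(ids)
      t <- t + 1
      up <- .adam_step(model$W, G, st, config$lr, t)
      model$W <- up$W; st <- up$st
      # dense layer Adam
      std$mw <- 0.9 * std$mw + 0.1 * gd$gw
      std$vw <- 0.999 * std$vw + 0.001 * gd$gw^2
      std$mb <- 0.9 * std$mb + 0.1 * gd$gb
      std$vb <- 0.999 * std$vb + 0.001 * gd$gb^2
      model$dense$w <- model$dense$w - config$lr *
        (std$mw / (1 - 0.9^t)) / (sqrt(std$vw / (1 - 0.999^t)) + 1e-8)
      model$dense$b <- model$dense$b - config$lr *
        (std$mb / (1 - 0.9^t)) / (sqrt(std$vb / (1 - 0.999^t)) + 1e-8)
    }
    trace[ep] <- mean(losses)
    if (ep %in% checkpoint_epochs) {
      mcopy <- model; mcopy$loss_trace <- trace[seq_len(ep)]
      checkpoints[[length(checkpoints) + 1L]] <- mcopy
    }
  }
  model$loss_trace <- trace
  model$checkpoints <- checkpoints
  model
}

#' Predict outcome probabilities with a trained CNN
#' @param model trained \code{CNN3D}.
#' @param volumes list of volumes/arrays on the model grid.
#' @return numeric vector of class-1 probabilities.
#' @export
predictCNN <- function(model, volumes) {
  vapply(volumes, function(v) .cnn_forward(model, v)$p, 0)
}
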