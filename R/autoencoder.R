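# 1D convolutional autoencoder for fitness-profile normalization.
#
# The network consumes one gene profile per sample (length = number of cell
# lines, one channel). Encoder: conv(1->10, k3, pad 1) -> maxpool(2) ->
# conv(10->20, k3, pad 1) -> maxpool(2) -> flatten -> linear(-> LS).
# Decoder: linear(LS -> flat) -> max-unpooling with the stored pooling
# indices -> transposed conv(20->10) -> unpooling -> transposed conv
# (10->1) -> final linear restoring the profile length. With stride 1 and
# padding 1 a transposed convolution is itself a length-preserving
# convolution, which is how it is parameterized here. Training is plain
# minibatch Adam on the mean squared reconstruction error, written out
# explicitly (forward caches + hand-derived gradients): the matrices are
# desk-scale and the implementation has no external dependencies, making
# seeded runs bit-reproducible.

#' Autoencoder configuration
#'
#' @param latentSize bottleneck width LS (>= 1); the onion grid dials
#'   `LS = 1, 2, 3, 4, 5, 10`.
#' @param epochs training epochs (default 1).
#' @param convChannels channels of the two encoder convolutions (10, 20).
#' @param kernelSize convolution kernel size (3).
#' @param poolSize pooling kernel size (2).
#' @param learningRate Adam step size (default 0.01).
#' @param batchSize minibatch size (default 32).
#' @param activation `"linear"` (default; the layer stack's only
#'   nonlinearity is then max pooling/unpooling) or `"relu"` after each
#'   convolution and the decoder's input linear layer.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return A named list of settings (class `"AeConfig"`).
#' @export
AeConfig <- function(latentSize = 1L, epochs = 1L, convChannels = c(10L, 20L),
                     kernelSize = 3L, poolSize = 2L, learningRate = 0.01,
                     batchSize = 32L, activation = c("linear", "relu"),
                     seed = 17L) {
    stopifnot(latentSize >= 1L, epochs >= 1L, length(convChannels) == 2L,
              kernelSize >= 1L, poolSize >= 2L, learningRate > 0,
              batchSize >= 1L)
    structure(list(latentSize = as.integer(latentSize),
                   epochs = as.integer(epochs),
                   convChannels = as.integer(convChannels),
                   kernelSize = as.integer(kernelSize),
                   poolSize = as.integer(poolSize),
                   learningRate = learningRate,
                   batchSize = as.integer(batchSize),
                   activation = match.arg(activation),
                   seed = as.integer(seed)),
              class = c("AeConfig", "list"))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.aeInitTensor <- function(dims, fanIn) {
    bound <- 1 / sqrt(fanIn)
    array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

#' Build an untrained convolutional autoencoder
#'
#' @param profileLength length of one input profile (number of conditions);
#'   must be >= 8 so both pooling stages are valid.
#' @param cfg an [AeConfig()].
#' @return A model handle (list of parameter arrays and shape bookkeeping),
#'   class `"onionAutoencoder"`.
#' @export
buildAutoencoder <- function(profileLength, cfg = AeConfig()) {
    L <- as.integer(profileLength)
    if (L < 8L)
        stop("profileLength must be >= 8 for two pooling stages", call. = FALSE)
    K <- cfg$kernelSize
    C1 <- cfg$convChannels[1L]; C2 <- cfg$convChannels[2L]
    LS <- cfg$latentSize
    L1 <- L %/% cfg$poolSize
    L2 <- L1 %/% cfg$poolSize
    FL <- C2 * L2
    params <- .withSeed(cfg$seed, list(
        W1 = .aeInitTensor(c(C1, 1L, K), 1 * K),
        b1 = as.numeric(.aeInitTensor(C1, 1 * K)),
        W2 = .aeInitTensor(c(C2, C1, K), C1 * K),
        b2 = as.numeric(.aeInitTensor(C2, C1 * K)),
        We = .aeInitTensor(c(LS, FL), FL),
        be = as.numeric(.aeInitTensor(LS, FL)),
        Wd = .aeInitTensor(c(FL, LS), LS),
        bd = as.numeric(.aeInitTensor(FL, LS)),
        W3 = .aeInitTensor(c(C1, C2, K), C2 * K),
        b3 = as.numeric(.aeInitTensor(C1, C2 * K)),
        W4 = .aeInitTensor(c(1L, C1, K), C1 * K),
        b4 = as.numeric(.aeInitTensor(1L, C1 * K)),
        Wf = .aeInitTensor(c(L, L), L),
        bf = as.numeric(.aeInitTensor(L, L))))
    structure(list(params = params, cfg = cfg,
                   dims = list(L = L, L1 = L1, L2 = L2, FL = FL,
                               C1 = C1, C2 = C2, K = K)),
              class = "onionAutoencoder")
}

# ---- primitive layers (x is [B, C, L] array) -------------------------------

.convPad1 <- function(x, W, b) {
    d <- dim(x); B <- d[1L]; Cin <- d[2L]; L <- d[3L]
    K <- dim(W)[3L]; Cout <- dim(W)[1L]
    pad <- (K - 1L) %/% 2L
    xp <- array(0, c(B, Cin, L + 2L * pad))
    xp[, , pad + seq_len(L)] <- x
    out <- array(0, c(B, Cout, L))
    for (co in seq_len(Cout)) {
        acc <- matrix(b[co], B, L)
        for (ci in seq_len(Cin))
            for (k in seq_len(K))
                acc <- acc + W[co, ci, k] *
                    matrix(xp[, ci, (k - 1L) + seq_len(L)], B, L)
        out[, co, ] <- acc
    }
    list(out = out, xp = xp)
}

.convPad1Backward <- function(dout, xp, W) {
    K <- dim(W)[3L]; Cout <- dim(W)[1L]; Cin <- dim(W)[2L]
    B <- dim(dout)[1L]; L <- dim(dout)[3L]
    pad <- (K - 1L) %/% 2L
    dW <- array(0, dim(W)); db <- numeric(Cout)
    dxp <- array(0, dim(xp))
    for (co in seq_len(Cout)) {
        g <- matrix(dout[, co, ], B, L)
        db[co] <- sum(g)
        for (ci in seq_len(Cin))
            for (k in seq_len(K)) {
                idx <- (k - 1L) + seq_len(L)
                dW[co, ci, k] <- sum(g * matrix(xp[, ci, idx], B, L))
                dxp[, ci, idx] <- dxp[, ci, idx] + W[co, ci, k] * g
            }
    }
    list(dx = dxp[, , pad + seq_len(L), drop = FALSE], dW = dW, db = db)
}

.linIndex <- function(B, C, posIdx) {
    # absolute linear indices into an array [B, C, L] for per-(b,c,t)
    # positions posIdx [B, C, T]
    d <- dim(posIdx); Tn <- d[3L]
    bIdx <- array(rep(seq_len(B), C * Tn), d)
    cIdx <- array(rep(rep(seq_len(C), each = B), Tn), d)
    bIdx + (cIdx - 1L) * B + (posIdx - 1L) * (B * C)
}

.maxPool2 <- function(x) {
    d <- dim(x); B <- d[1L]; C <- d[2L]; L <- d[3L]
    Lp <- L %/% 2L
    a <- x[, , seq(1L, 2L * Lp, by = 2L), drop = FALSE]
    b <- x[, , seq(2L, 2L * Lp, by = 2L), drop = FALSE]
    takeB <- b > a
    out <- a; out[takeB] <- b[takeB]
    pos <- array(rep(seq(1L, 2L * Lp, by = 2L), each = B * C), c(B, C, Lp))
    pos[takeB] <- pos[takeB] + 1L
    list(out = out, pos = pos, L = L)
}

.maxPool2Backward <- function(dout, pool) {
    d <- dim(dout); B <- d[1L]; C <- d[2L]
    dx <- array(0, c(B, C, pool$L))
    dx[.linIndex(B, C, pool$pos)] <- dout
    dx
}

.maxUnpool2 <- function(z, pos, Lout) {
    d <- dim(z); B <- d[1L]; C <- d[2L]
    y <- array(0, c(B, C, Lout))
    y[.linIndex(B, C, pos)] <- z
    y
}

.maxUnpool2Backward <- function(dy, pos) {
    d <- dim(dy); B <- d[1L]; C <- d[2L]
    array(dy[.linIndex(B, C, pos)], dim(pos))
}

# ---- forward / backward ----------------------------------------------------

# Full forward pass with caches; X is a [B, L] matrix of profiles.
.aeForward <- function(model, X) {
    p <- model$params; dm <- model$dims
    B <- nrow(X)
    x <- array(X, c(B, 1L, dm$L))
    act <- isTRUE(model$cfg$activation == "relu")
    c1 <- .convPad1(x, p$W1, p$b1)
    m1 <- if (act) c1$out > 0 else array(TRUE, dim(c1$out))
    h1 <- c1$out * m1
    p1 <- .maxPool2(h1)
    c2 <- .convPad1(p1$out, p$W2, p$b2)
    m2 <- if (act) c2$out > 0 else array(TRUE, dim(c2$out))
    h2 <- c2$out * m2
    p2 <- .maxPool2(h2)
    f <- matrix(p2$out, B, dm$FL)
    z <- f %*% t(p$We) + rep(p$be, each = B)
    gPre <- z %*% t(p$Wd) + rep(p$bd, each = B)
    mg <- if (act) gPre > 0 else matrix(TRUE, nrow(gPre), ncol(gPre))
    g <- gPre * mg
    u2 <- .maxUnpool2(array(g, c(B, dm$C2, dm$L2)), p2$pos, dim(h2)[3L])
    c3 <- .convPad1(u2, p$W3, p$b3)
    m3 <- if (act) c3$out > 0 else array(TRUE, dim(c3$out))
    h3 <- c3$out * m3
    u1 <- .maxUnpool2(h3, p1$pos, dim(h1)[3L])
    c4 <- .convPad1(u1, p$W4, p$b4)
    h4 <- matrix(c4$out, B, dm$L)
    out <- h4 %*% t(p$Wf) + rep(p$bf, each = B)
    list(out = out, z = z, caches = list(
        x = x, c1 = c1, m1 = m1, p1 = p1, c2 = c2, m2 = m2, p2 = p2,
        f = f, mg = mg, u2 = u2, c3 = c3, m3 = m3, u1 = u1, c4 = c4,
        h4 = h4, B = B))
}

.aeBackward <- function(model, fw, dout) {
    p <- model$params; dm <- model$dims; ch <- fw$caches
    B <- ch$B
    g <- list()
    g$Wf <- t(dout) %*% ch$h4
    g$bf <- colSums(dout)
    dh4 <- dout %*% p$Wf
    b4 <- .convPad1Backward(array(dh4, c(B, 1L, dm$L)), ch$c4$xp, p$W4)
    g$W4 <- b4$dW; g$b4 <- b4$db
    dh3 <- .maxUnpool2Backward(b4$dx, ch$p1$pos)
    dc3 <- dh3 * ch$m3
    b3 <- .convPad1Backward(dc3, ch$c3$xp, p$W3)
    g$W3 <- b3$dW; g$b3 <- b3$db
    dg3d <- .maxUnpool2Backward(b3$dx, ch$p2$pos)   # [B, C2, L2]
    dg <- matrix(dg3d, B, dm$FL) * matrix(ch$mg, B, dm$FL)
    g$Wd <- t(dg) %*% fw$z
    g$bd <- colSums(dg)
    dz <- dg %*% p$Wd
    g$We <- t(dz) %*% ch$f
    g$be <- colSums(dz)
    df <- dz %*% p$We
    dp2 <- array(df, c(B, dm$C2, dm$L2))
    dh2 <- .maxPool2Backward(dp2, ch$p2)
    dc2 <- dh2 * ch$m2
    b2 <- .convPad1Backward(dc2, ch$c2$xp, p$W2)
    g$W2 <- b2$dW; g$b2 <- b2$db
    dh1 <- .maxPool2Backward(b2$dx, ch$p1)
    dc1 <- dh1 * ch$m1
    b1 <- .convPad1Backward(dc1, ch$c1$xp, p$W1)
    g$W1 <- b1$dW; g$b1 <- b1$db
    g[names(model$params)]
}

#' Run the autoencoder forward
#'
#' @param model an `"onionAutoencoder"` (from [buildAutoencoder()] or
#'   [trainAutoencoder()]).
#' @param X matrix of profiles, one per row (columns = conditions).
#' @param batchSize evaluation batch size.
#' @return matrix of reconstructed profiles, same shape as `X`.
#' @export
aeReconstruct <- function(model, X, batchSize = 256L) {
    out <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
    starts <- seq(1L, nrow(X), by = batchSize)
    for (s in starts) {
        idx <- s:min(s + batchSize - 1L, nrow(X))
        out[idx, ] <- .aeForward(model, X[idx, , drop = FALSE])$out
    }
    out
}

#' Train an autoencoder on profiles
#'
#' Minibatch Adam on the mean squared reconstruction error; the sample
#' order is reshuffled every epoch under the model seed, so identical
#' inputs and configuration reproduce identical weights.
#'
#' @param model an `"onionAutoencoder"`.
#' @param X matrix of training profiles (rows = samples).
#' @return The trained model, with an attached `history` element (per-epoch
#'   mean training loss) and `lossStart` (full-data loss of the untrained
#'   model).
#' @export
trainAutoencoder <- function(model, X) {
    cfg <- model$cfg
    mseFull <- function(mod) mean((aeReconstruct(mod, X) - X)^2)
    model$lossStart <- mseFull(model)
    mAdam <- lapply(model$params, function(w) w * 0)
    vAdam <- lapply(model$params, function(w) w * 0)
    beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
    tStep <- 0L
    history <- numeric(cfg$epochs)
    order <- .withSeed(cfg$seed + 1L,
                       replicate(cfg$epochs, sample.int(nrow(X)),
                                 simplify = FALSE))
    for (ep in seq_len(cfg$epochs)) {
        perm <- order[[ep]]
        losses <- c()
        for (s in seq(1L, nrow(X), by = cfg$batchSize)) {
            idx <- perm[s:min(s + cfg$batchSize - 1L, nrow(X))]
            Xb <- X[idx, , drop = FALSE]
            fw <- .aeForward(model, Xb)
            err <- fw$out - Xb
            losses <- c(losses, mean(err^2))
            if (!is.finite(losses[length(losses)]))
                stop("non-finite training loss (lr = ", cfg$learningRate,
                     ", batch starting at ", s, ")", call. = FALSE)
            dout <- 2 * err / length(err)
            grads <- .aeBackward(model, fw, dout)
            tStep <- tStep + 1L
            for (nm in names(model$params)) {
                mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * grads[[nm]]
                vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * grads[[nm]]^2
                mh <- mAdam[[nm]] / (1 - beta1^tStep)
                vh <- vAdam[[nm]] / (1 - beta2^tStep)
                model$params[[nm]] <- model$params[[nm]] -
                    cfg$learningRate * mh / (sqrt(vh) + epsA)
            }
        }
        history[ep] <- mean(losses)
    }
    model$history <- history
    model$lossEnd <- mseFull(model)
    model
}

#' Autoencoder normalization
#'
#' Trains the convolutional autoencoder on preprocessed gene profiles (see
#' [aePreprocess()]) for `cfg$epochs` epochs, computes the reconstruction
#' of every profile, and subtracts it: the residual is the AE-normalized
#' layer, the decoder output the AE-reconstructed layer. Both live in the
#' preprocessed value space.
#'
#' @param x a [GeneEffectMatrix-class]; preprocessed already if
#'   `preprocessed = TRUE`, otherwise [aePreprocess()] is applied first.
#' @param cfg an [AeConfig()].
#' @param preprocessed set `TRUE` when `x` already went through
#'   [aePreprocess()].
#' @return list with `normalized` and `reconstructed`
#'   [NormalizedLayer-class] objects (`method = "ae"` /
#'   `"ae_reconstructed"`, `hyperparameter = latentSize`), the trained
#'   `model`, and `lossStart`/`lossEnd` mean squared errors.
#' @export
aeNormalize <- function(x, cfg = AeConfig(), preprocessed = FALSE) {
    stopifnot(is(x, "GeneEffectMatrix"))
    pre <- if (preprocessed) x else aePreprocess(x)
    X <- scoreMatrix(pre, "genes_as_rows")
    model <- buildAutoencoder(ncol(X), cfg)
    model <- trainAutoencoder(model, X)
    R <- aeReconstruct(model, X)
    list(normalized = NormalizedLayer(X - R, pre, "ae", cfg$latentSize),
         reconstructed = NormalizedLayer(R, pre, "ae_reconstructed",
                                         cfg$latentSize),
         model = model, lossStart = model$lossStart, lossEnd = model$lossEnd)
}
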