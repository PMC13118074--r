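# 1-D convolutional neural network over the spectral axis, implemented in
# base R with exact backpropagation and Adam. Architecture: three conv
# blocks (kernel length 5, 8 feature maps, batch normalization, ReLU, same
# padding, stride 1), global average pooling over the spectral dimension,
# dense layers 64 and 16 with ReLU, and a 2-way softmax output trained with
# cross-entropy.

KERNEL <- 5L
CHANNELS <- 8L

# ---- layer primitives -------------------------------------------------

# conv over (N, L, Cin) -> (N, L, Cout), same padding, stride 1
convForward <- function(A, W, b) {
  d <- dim(A); n <- d[1L]; l <- d[2L]; cin <- d[3L]
  cout <- dim(W)[3L]
  pad <- (KERNEL - 1L) %/% 2L
  Ap <- array(0, c(n, l + 2L * pad, cin))
  Ap[, (pad + 1L):(pad + l), ] <- A
  Hf <- matrix(rep(b, each = n * l), n * l, cout)
  for (k in seq_len(KERNEL)) {
    Ak <- Ap[, k:(k + l - 1L), , drop = FALSE]
    dim(Ak) <- c(n * l, cin)
    Hf <- Hf + Ak %*% matrix(W[k, , ], cin, cout)
  }
  list(out = array(Hf, c(n, l, cout)), Ap = Ap)
}

convBackward <- function(dOut, cache, W) {
  d <- dim(dOut); n <- d[1L]; l <- d[2L]; cout <- d[3L]
  cin <- dim(W)[2L]
  pad <- (KERNEL - 1L) %/% 2L
  dOutF <- matrix(dOut, n * l, cout)
  dW <- array(0, dim(W)); dAp <- array(0, dim(cache$Ap))
  for (k in seq_len(KERNEL)) {
    Ak <- cache$Ap[, k:(k + l - 1L), , drop = FALSE]
    dim(Ak) <- c(n * l, cin)
    dW[k, , ] <- crossprod(Ak, dOutF)
    dAk <- dOutF %*% t(matrix(W[k, , ], cin, cout))
    dAp[, k:(k + l - 1L), ] <- dAp[, k:(k + l - 1L), , drop = FALSE] +
      array(dAk, c(n, l, cin))
  }
  list(dA = dAp[, (pad + 1L):(pad + l), , drop = FALSE],
       dW = dW, db = colSums(dOutF))
}

bnForward <- function(A, gamma, beta, running, training, momentum = 0.9,
                      epsBN = 1e-5) {
  d <- dim(A); m <- d[1L] * d[2L]; ch <- d[3L]
  Af <- matrix(A, m, ch)
  if (training) {
    mu <- colMeans(Af)
    vr <- colMeans(Af^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * vr
  } else {
    mu <- running$mean; vr <- running$var
  }
  istd <- 1 / sqrt(vr + epsBN)
  xhat <- (Af - rep(mu, each = m)) * rep(istd, each = m)
  out <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(out = array(out, d), xhat = xhat, istd = istd, running = running, dims = d)
}

bnBackward <- function(dOut, cache, gamma) {
  d <- cache$dims; m <- d[1L] * d[2L]; ch <- d[3L]
  dY <- matrix(dOut, m, ch)
  dGamma <- colSums(dY * cache$xhat)
  dBeta <- colSums(dY)
  dXhat <- dY * rep(gamma, each = m)
  dX <- (dXhat - rep(colMeans(dXhat), each = m) -
           cache$xhat * rep(colMeans(dXhat * cache$xhat), each = m)) *
    rep(cache$istd, each = m)
  list(dA = array(dX, d), dGamma = dGamma, dBeta = dBeta)
}

# ---- network ----------------------------------------------------------

nnInitParams <- function(bands, seed) {
  withSeed(seed, {
    he <- function(fanIn, dims) array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)
    cin <- c(1L, CHANNELS, CHANNELS)
    params <- list()
    for (j in 1:3) {
      params[[paste0("W", j)]] <- he(KERNEL * cin[j], c(KERNEL, cin[j], CHANNELS))
      params[[paste0("b", j)]] <- numeric(CHANNELS)
      params[[paste0("g", j)]] <- rep(1, CHANNELS)
      params[[paste0("be", j)]] <- numeric(CHANNELS)
    }
    params$Wd1 <- he(CHANNELS, c(CHANNELS, 64L)); params$bd1 <- numeric(64L)
    params$Wd2 <- he(64L, c(64L, 16L)); params$bd2 <- numeric(16L)
    params$Wd3 <- he(16L, c(16L, 2L)); params$bd3 <- numeric(2L)
    running <- lapply(1:3, function(j) list(mean = numeric(CHANNELS),
                                            var = rep(1, CHANNELS)))
    list(params = params, running = running, bands = as.integer(bands))
  })
}

nnForward <- function(net, X, training = FALSE) {
  n <- nrow(X)
  A <- array(X, c(n, ncol(X), 1L))
  caches <- list()
  running <- net$running
  for (j in 1:3) {
    cv <- convForward(A, net$params[[paste0("W", j)]], net$params[[paste0("b", j)]])
    bn <- bnForward(cv$out, net$params[[paste0("g", j)]],
                    net$params[[paste0("be", j)]], running[[j]], training)
    running[[j]] <- bn$running
    relu <- pmax(bn$out, 0)
    caches[[j]] <- list(conv = cv, bn = bn, preRelu = bn$out)
    A <- relu
  }
  G <- apply(A, c(1, 3), mean)              # global average pool -> n x C
  Z1 <- G %*% net$params$Wd1 + rep(net$params$bd1, each = n); H1 <- pmax(Z1, 0)
  Z2 <- H1 %*% net$params$Wd2 + rep(net$params$bd2, each = n); H2 <- pmax(Z2, 0)
  logits <- H2 %*% net$params$Wd3 + rep(net$params$bd3, each = n)
  mx <- pmax(logits[, 1L], logits[, 2L])
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, caches = caches, A3 = A, G = G,
       Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, running = running)
}

nnBackward <- function(net, fw, X, yIdx) {
  n <- nrow(X)
  grads <- list()
  dLogits <- fw$probs
  dLogits[cbind(seq_len(n), yIdx)] <- dLogits[cbind(seq_len(n), yIdx)] - 1
  dLogits <- dLogits / n
  grads$Wd3 <- crossprod(fw$H2, dLogits); grads$bd3 <- colSums(dLogits)
  dH2 <- dLogits %*% t(net$params$Wd3) * (fw$Z2 > 0)
  grads$Wd2 <- crossprod(fw$H1, dH2); grads$bd2 <- colSums(dH2)
  dH1 <- dH2 %*% t(net$params$Wd2) * (fw$Z1 > 0)
  grads$Wd1 <- crossprod(fw$G, dH1); grads$bd1 <- colSums(dH1)
  dG <- dH1 %*% t(net$params$Wd1)
  l <- dim(fw$A3)[2L]
  dA <- array(0, dim(fw$A3))
  for (ch in seq_len(CHANNELS)) dA[, , ch] <- dG[, ch] / l
  for (j in 3:1) {
    dA <- dA * (fw$caches[[j]]$preRelu > 0)
    bb <- bnBackward(dA, fw$caches[[j]]$bn, net$params[[paste0("g", j)]])
    grads[[paste0("g", j)]] <- bb$dGamma
    grads[[paste0("be", j)]] <- bb$dBeta
    cb <- convBackward(bb$dA, fw$caches[[j]]$conv, net$params[[paste0("W", j)]])
    grads[[paste0("W", j)]] <- cb$dW
    grads[[paste0("b", j)]] <- cb$db
    dA <- cb$dA
  }
  grads
}

adamStep <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     epsA = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + epsA)
  }
  list(net = net, state = state)
}

#' Closed-form parameter count of the spectral CNN
#'
#' Sum of learnable weights and biases of the architecture (conv kernels
#' and biases, batch-norm scale and shift, dense layers) for a given input
#' band count. The count is independent of the band count because the
#' global average pool collapses the spectral dimension.
#'
#' @param bands number of input bands.
#' @return integer parameter count.
#' @export
nnParameterCount <- function(bands = 81L) {
  net <- nnInitParams(bands, seed = 1L)
  sum(vapply(net$params, length, integer(1)))
}

#' Train the 1-D convolutional pixel classifier
#'
#' Trains the spectral CNN (three conv blocks of kernel length 5 with 8
#' feature maps, batch normalization and ReLU; global average pooling;
#' dense 64 and 16 with ReLU; 2-way softmax) with Adam at initial learning
#' rate 0.001 and mini-batches of 4096 spectra (capped at the dataset
#' size), minimizing cross-entropy. Initialization, batch shuffling and
#' batch-norm statistics are all fixed by the seed, so repeated training on
#' the same data is bit-reproducible.
#'
#' @param train a [PixelDataset] with both classes; spectra must have at
#'   least 5 bands.
#' @param epochs training epochs (default 30, no early stopping).
#' @param seed integer seed.
#' @param batchSize mini-batch size (default 4096).
#' @param lr initial Adam learning rate (default 0.001).
#' @return An [NNModel]; `metadata$finalLoss` holds the last epoch's mean
#'   training cross-entropy.
#' @export
trainNN <- function(train, epochs = 30L, seed = 1L, batchSize = 4096L, lr = 1e-3) {
  stopifnot(is(train, "PixelDataset"))
  if (ncol(train@spectra) < KERNEL)
    stop("spectra must have at least as many bands as the kernel length (5)")
  if (nlevels(droplevels(train@labels)) < 2L)
    stop("training set must contain both classes")
  X <- train@spectra
  yIdx <- as.integer(train@labels)          # 1 = healthy, 2 = defect
  n <- nrow(X)
  bs <- min(as.integer(batchSize), n)
  net <- nnInitParams(ncol(X), deriveSeed(seed, "nn-init"))
  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  t <- 0L; lastLoss <- NA_real_
  withSeed(deriveSeed(seed, "nn-shuffle"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = bs)) {
        ix <- ord[start:min(start + bs - 1L, n)]
        fw <- nnForward(net, X[ix, , drop = FALSE], training = TRUE)
        net$running <- fw$running
        p <- fw$probs[cbind(seq_along(ix), yIdx[ix])]
        losses <- c(losses, -mean(log(pmax(p, 1e-12))))
        grads <- nnBackward(net, fw, X[ix, , drop = FALSE], yIdx[ix])
        t <- t + 1L
        st <- adamStep(net, grads, state, lr, t)
        net <- st$net; state <- st$state
      }
      lastLoss <- mean(losses)
    }
  })
  tab <- table(train@labels)
  new("NNModel", method = "nn", seed = as.integer(seed),
      metadata = list(nHealthy = tab[["healthy"]], nDefect = tab[["defect"]],
                      nBands = ncol(X), epochs = as.integer(epochs),
                      batchSize = bs, learningRate = lr,
                      finalLoss = lastLoss,
                      parameterCount = sum(vapply(net$params, length, integer(1)))),
      net = net)
}

#' @rdname predictLabels
setMethod("predictLabels", "NNModel", function(model, spectra, ...) {
  if (ncol(spectra) != model@net$bands)
    stop("band count mismatch between model and spectra")
  # predict in blocks to bound memory
  n <- nrow(spectra)
  out <- integer(n)
  for (start in seq(1L, n, by = 8192L)) {
    ix <- start:min(start + 8191L, n)
    fw <- nnForward(model@net, spectra[ix, , drop = FALSE], training = FALSE)
    out[ix] <- max.col(fw$probs)
  }
  factor(c("healthy", "defect")[out], levels = c("healthy", "defect"))
})
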