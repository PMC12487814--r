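# Conditional VAE for one modality.
#
# Architecture (per modality):
#   encoder:   [log1p depth-normalized profile, time enc, condition, batch]
#              -> 2 ReLU hidden layers -> (mu, logVar) of the L-dim
#              cell-identity posterior
#   interaction: [z, time enc, condition] -> 1 ReLU hidden layer -> L-dim
#              time-aware embedding (tied across modalities when coupled)
#   decoder:   [time-aware embedding, batch] -> 2 ReLU hidden layers ->
#              RNA: per-gene softmax mean fractions + dropout logits,
#                   with a free per-gene log dispersion;
#              ATAC: per-peak logits (+ per-cell coverage offset)
#   discriminator: z -> 2 ReLU hidden layers -> logits over observed
#              training time points (RNA model only)
#
# Hidden widths are the rounded geometric mean of the data dimension and
# the latent dimension.

.LV_CLAMP <- 10  # |logVar| clamp inside the encoder head

# Precompute the per-cell side information used by every pass.
.prep_data <- function(x, spec, conditionLevels, batchLevels,
                       timeClasses, depthScale) {
  counts <- SummarizedExperiment::assay(x, "counts")
  depth <- Matrix::colSums(counts)
  tm <- timePoint(x)
  list(counts = counts, depth = depth, time = tm,
       tenc = sinusoidalEncode(tm, spec),
       con = oneHot(conditionLabel(x), conditionLevels),
       bat = oneHot(batchLabel(x), batchLevels),
       tclass = match(tm, timeClasses),
       depthScale = depthScale, ids = colnames(x))
}

.batch_input <- function(dat, idx) {
  X <- as.matrix(Matrix::t(dat$counts[, idx, drop = FALSE]))
  depth <- dat$depth[idx]
  list(X = X, depth = depth,
       xin = log1p(X / depth * dat$depthScale),
       tenc = dat$tenc[idx, , drop = FALSE],
       con = dat$con[idx, , drop = FALSE],
       bat = dat$bat[idx, , drop = FALSE],
       tclass = dat$tclass[idx])
}

.encode_batch <- function(params, bi, L) {
  A <- .mlp_forward(params$enc, cbind(bi$xin, bi$tenc, bi$con, bi$bat))
  out <- A[[length(A)]]
  mu <- out[, seq_len(L), drop = FALSE]
  lv_raw <- out[, L + seq_len(L), drop = FALSE]
  lv <- pmin(pmax(lv_raw, -.LV_CLAMP), .LV_CLAMP)
  list(A = A, mu = mu, lv = lv, lv_mask = abs(lv_raw) < .LV_CLAMP)
}

.interact <- function(params, z, tenc, con) {
  A <- .mlp_forward(params$inter, cbind(z, tenc, con))
  list(A = A, e = A[[length(A)]])
}

# RNA decoder head: softmax mean fractions + dropout logits.
.decode_rna <- function(params, e, bat) {
  A <- .mlp_forward(params$dec, cbind(e, bat))
  out <- A[[length(A)]]
  G <- ncol(out) / 2
  s <- out[, seq_len(G), drop = FALSE]
  gl <- out[, G + seq_len(G), drop = FALSE]
  list(A = A, frac = .softmax(s), droplogit = gl)
}

.decode_atac <- function(params, e, bat, covin) {
  A <- .mlp_forward(params$dec, cbind(e, bat))
  # covin is an n x 1 per-cell coverage offset, broadcast across peaks
  logits <- A[[length(A)]] + as.vector(params$cov_a * covin)
  list(A = A, logits = logits, prob = plogis(logits))
}

# Reconstruction + KL losses and their gradients for one RNA batch.
# Returns loss pieces, gradients for the generator parameter group, and
# the sampled z (for the adversarial terms handled by the caller).
.rna_forward <- function(params, bi, L, eps = NULL) {
  enc <- .encode_batch(params, bi, L)
  n <- nrow(enc$mu)
  if (is.null(eps)) eps <- matrix(0, n, L)
  sig <- exp(0.5 * enc$lv)
  z <- enc$mu + sig * eps
  inter <- .interact(params, z, bi$tenc, bi$con)
  dec <- .decode_rna(params, inter$e, bi$bat)
  theta_row <- exp(params$log_theta)
  mu_count <- bi$depth * dec$frac
  theta <- matrix(theta_row, n, length(theta_row), byrow = TRUE)
  ll <- zinbLogLik(bi$X, mu_count, theta, plogis(dec$droplogit))
  kl <- klNormal(enc$mu, enc$lv)
  list(enc = enc, eps = eps, z = z, inter = inter, dec = dec,
       mu_count = mu_count, theta = theta,
       rec_loss = -mean(ll), kl_loss = mean(kl))
}

# Backward pass for the generator objective
#   mean(-zinb loglik) + beta * mean(KL) + adversarial term
# with discriminator parameters frozen. dz_extra injects gradients
# arriving at the sampled z; dmu_extra injects gradients arriving at
# the posterior mean directly (the adversarial term acts there: the
# cell-identity embedding whose time-invariance matters is the mean).
.rna_backward <- function(params, bi, fw, L, beta = 1, dz_extra = NULL,
                          dmu_extra = NULL) {
  n <- nrow(fw$z)
  zg <- .zinb_grads(bi$X, fw$mu_count, fw$theta, fw$dec$droplogit)
  dLmu <- -zg$dmu / n
  rs <- rowSums(dLmu * fw$dec$frac)
  dS <- bi$depth * fw$dec$frac * (dLmu - rs)
  dGL <- -zg$dlogit / n
  dlog_theta <- colSums(-zg$dlogtheta / n)
  bdec <- .mlp_backward(params$dec, fw$dec$A, cbind(dS, dGL))
  dE <- bdec$dX[, seq_len(L), drop = FALSE]
  binter <- .mlp_backward(params$inter, fw$inter$A, dE)
  dz <- binter$dX[, seq_len(L), drop = FALSE]
  if (!is.null(dz_extra)) dz <- dz + dz_extra
  dmu <- dz + beta * fw$enc$mu / n
  if (!is.null(dmu_extra)) dmu <- dmu + dmu_extra
  dlv <- dz * fw$eps * 0.5 * exp(0.5 * fw$enc$lv) +
    beta * 0.5 * (exp(fw$enc$lv) - 1) / n
  dlv <- dlv * fw$enc$lv_mask
  benc <- .mlp_backward(params$enc, fw$enc$A, cbind(dmu, dlv))
  list(enc = benc$grads, inter = binter$grads, dec = bdec$grads,
       log_theta = dlog_theta)
}

# Cross-entropy of the time discriminator on embeddings z. Returns the
# CE against the true time classes (with gradients wrt the
# discriminator parameters and wrt z) and, for the generator's
# adversarial update, the gradient wrt z of the cross-entropy against
# the *uniform* distribution over time classes. Descending the latter
# drives the discriminator's output toward uninformative, which removes
# time information from z; ascending the former (the literal min-max
# surrogate) merely reshuffles it and is unstable.
.disc_forward_backward <- function(disc, z, tclass) {
  A <- .mlp_forward(disc, z)
  logits <- A[[length(A)]]
  P <- .softmax(logits)
  n <- nrow(z); K <- ncol(logits)
  ce <- -mean(log(pmax(P[cbind(seq_len(n), tclass)], 1e-12)))
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), tclass)] <- 1
  b <- .mlp_backward(disc, A, (P - Y) / n)
  b_unif <- .mlp_backward(disc, A, (P - 1 / K) / n)
  list(ce = ce, grads = b$grads, dz = b$dX, dz_unif = b_unif$dX, probs = P)
}

.init_rna_params <- function(G, L, d, nc, nb, nT) {
  h <- .hidden_dim(G, L)
  hi <- .hidden_dim(L + d + nc, L)
  hd <- .hidden_dim(max(L, nT), max(8L, nT))
  list(enc = .mlp_init(c(G + d + nc + nb, h, h, 2 * L)),
       inter = .mlp_init(c(L + d + nc, hi, L)),
       dec = .mlp_init(c(L + nb, h, h, 2 * G)),
       disc = .mlp_init(c(L, hd, hd, nT)),
       log_theta = rep(log(25), G))
}

#' Train the temporal conditional VAE on one scRNA-seq data set
#'
#' Fits the conditional VAE: a ZINB reconstruction likelihood plus the
#' KL to a standard-normal prior (the reconstruction/KL objective), with
#' an adversarial time discriminator trained alternately against the
#' encoder so that cell-identity embeddings carry no time information.
#' The discriminator is fit on the posterior-mean embeddings
#' (`discSteps` updates per generator step), and the generator update
#' adds `advWeight` times the gradient of the cross-entropy between
#' the discriminator's output and the uniform distribution over time
#' classes -- the confusion form of the adversarial objective, which
#' (unlike ascending the true-class cross-entropy) actively removes
#' time information. `advWeight` is relative to the reconstruction
#' loss summed over genes; the default keeps the discriminator near
#' chance on typical fixtures while leaving reconstruction intact.
#' Training uses Adam, minibatches, a linear KL warm-up, and early
#' stopping on the validation reconstruction loss.
#'
#' @param x a [TemporalProfiles-class] with modality `"rna"`.
#' @param split optional [SplitPlan-class]; built from `holdoutTimes`
#'   with [makeSplit()] when absent.
#' @param holdoutTimes times (days) to exclude entirely (test set).
#' @param latentDim dimension L of the cell-identity embedding
#'   (default 50).
#' @param timeDim sinusoidal time-encoding dimension (default 50).
#' @param minWavelength minimum encoding wavelength, days (default 1).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize minibatch size (default 128).
#' @param maxEpochs,patience early-stopping controls: training stops
#'   after `patience` epochs without validation improvement.
#' @param klWarmup epochs over which the KL weight ramps 0 to 1.
#' @param advWeight weight of the adversarial term in the generator
#'   objective (default 100).
#' @param discSteps discriminator updates per generator step (default 5).
#' @param seed integer seed governing initialization, shuffling and
#'   posterior sampling.
#' @param verbose print per-epoch losses.
#' @return A [TemporalVAE-class].
#' @export
trainTemporalVAE <- function(x, split = NULL, holdoutTimes = numeric(0),
                             latentDim = 50, timeDim = 50, minWavelength = 1,
                             learningRate = 1e-3, batchSize = 128,
                             maxEpochs = 300, patience = 10, klWarmup = 10,
                             advWeight = 100, discSteps = 5, seed = 1,
                             verbose = FALSE) {
  stopifnot(methods::is(x, "TemporalProfiles"))
  if (modality(x) != "rna")
    stop("trainTemporalVAE models scRNA-seq counts; use trainMultimodal for ATAC")
  if (is.null(split)) split <- makeSplit(x, holdoutTimes, seed = seed)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  spec <- timeEncoding(timeDim, minWavelength)
  conditionLevels <- sort(unique(conditionLabel(x)))
  batchLevels <- sort(unique(batchLabel(x)))
  tr <- match(trainIds(split), colnames(x))
  va <- match(valIds(split), colnames(x))
  timeClasses <- sort(unique(timePoint(x)[tr]))
  depthScale <- median(Matrix::colSums(SummarizedExperiment::assay(x, "counts"))[tr])
  dat <- .prep_data(x, spec, conditionLevels, batchLevels, timeClasses, depthScale)
  G <- nrow(x); L <- latentDim
  params <- .init_rna_params(G, L, spec@d, length(conditionLevels),
                             length(batchLevels), length(timeClasses))
  gen_group <- c("enc", "inter", "dec", "log_theta")
  opt_gen <- .adam_new(params[gen_group])
  opt_disc <- .adam_new(params["disc"])
  best <- list(loss = Inf, params = params, epoch = 0)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), disc_loss = numeric(0))
  for (epoch in seq_len(maxEpochs)) {
    beta <- if (klWarmup > 0) min(1, epoch / klWarmup) else 1
    ord <- sample(tr)
    nb_batches <- ceiling(length(ord) / batchSize)
    ep_loss <- 0; ep_disc <- 0
    for (b in seq_len(nb_batches)) {
      idx <- ord[((b - 1) * batchSize + 1):min(b * batchSize, length(ord))]
      bi <- .batch_input(dat, idx)
      n <- length(idx)
      # discriminator step(s) on the posterior-mean embeddings
      # (encoder frozen: the embedding is detached)
      enc <- .encode_batch(params, bi, L)
      for (ds in seq_len(discSteps)) {
        dfb <- .disc_forward_backward(params$disc, enc$mu, bi$tclass)
        up <- .adam_step(params["disc"], list(disc = dfb$grads), opt_disc,
                         learningRate)
        params$disc <- up$params$disc; opt_disc <- up$state
      }
      # generator step (discriminator frozen)
      eps <- matrix(rnorm(n * L), n, L)
      fw <- .rna_forward(params, bi, L, eps)
      adv <- .disc_forward_backward(params$disc, fw$enc$mu, bi$tclass)
      grads <- .rna_backward(params, bi, fw, L, beta,
                             dmu_extra = advWeight * adv$dz_unif)
      up <- .adam_step(params[gen_group], grads, opt_gen, learningRate)
      params[gen_group] <- up$params; opt_gen <- up$state
      ep_loss <- ep_loss + (fw$rec_loss + beta * fw$kl_loss) * n
      ep_disc <- ep_disc + adv$ce * n
    }
    ep_loss <- ep_loss / length(ord); ep_disc <- ep_disc / length(ord)
    vl <- .rna_val_loss(params, dat, va, L)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = vl, disc_loss = ep_disc))
    if (verbose)
      message(sprintf("epoch %3d | train %.3f | val %.3f | disc %.3f",
                      epoch, ep_loss, vl, ep_disc))
    if (is.finite(vl) && vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  methods::new("TemporalVAE", modality = "rna", featureIds = rownames(x),
               latentDim = as.numeric(L), timeSpec = spec,
               conditionLevels = conditionLevels, batchLevels = batchLevels,
               timeClasses = timeClasses, params = best$params,
               config = list(depthScale = depthScale,
                             learningRate = learningRate,
                             batchSize = batchSize, klWarmup = klWarmup,
                             advWeight = advWeight, patience = patience,
                             maxEpochs = maxEpochs, seed = seed),
               history = hist, seed = as.numeric(seed))
}

.rna_val_loss <- function(params, dat, idx, L) {
  if (!length(idx)) return(NA_real_)
  bi <- .batch_input(dat, idx)
  fw <- .rna_forward(params, bi, L, eps = NULL)  # posterior mean
  fw$rec_loss + fw$kl_loss
}

.check_model_data <- function(model, x) {
  if (!identical(model@featureIds, rownames(x)))
    stop("feature ids/order differ from the model's training features")
}

.model_dat <- function(model, x) {
  .check_model_data(model, x)
  .prep_data(x, model@timeSpec, model@conditionLevels, model@batchLevels,
             model@timeClasses, model@params$depthScale %||%
               model@config$depthScale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cell_idx <- function(x, cells) {
  if (is.null(cells)) return(seq_len(ncol(x)))
  idx <- if (is.character(cells)) match(cells, colnames(x)) else cells
  if (anyNA(idx)) stop("unknown cell id(s)")
  idx
}

#' Encode cells into the cell-identity posterior
#'
#' Deterministic given the model: returns the posterior mean and log
#' variance of each cell's identity embedding. Sampled embeddings are
#' `mean + exp(logVar / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param model a [TemporalVAE-class].
#' @param x a [TemporalProfiles-class] with the model's features.
#' @param cells optional cell ids or indices (default: all).
#' @return list with matrices `mean` and `logVar` (cells x L).
#' @export
encodeCells <- function(model, x, cells = NULL) {
  dat <- .model_dat(model, x)
  idx <- .cell_idx(x, cells)
  bi <- .batch_input(dat, idx)
  enc <- .encode_batch(model@params, bi, model@latentDim)
  rownames(enc$mu) <- rownames(enc$lv) <- colnames(x)[idx]
  list(mean = enc$mu, logVar = enc$lv)
}

#' Time-aware embeddings at a target time and condition
#'
#' Passes cell-identity embeddings through the temporal interaction
#' layer at a chosen time/condition, yielding the L-dimensional
#' time-aware embedding that feeds the decoder.
#'
#' @inheritParams encodeCells
#' @param tTarget target time(s) in days (default: each cell's own).
#' @param conditionTarget target condition (default: each cell's own).
#' @return cells x L matrix.
#' @export
timeAwareEmbedding <- function(model, x, cells = NULL, tTarget = NULL,
                               conditionTarget = NULL) {
  dat <- .model_dat(model, x)
  idx <- .cell_idx(x, cells)
  bi <- .batch_input(dat, idx)
  enc <- .encode_batch(model@params, bi, model@latentDim)
  tt <- if (is.null(tTarget)) dat$time[idx] else rep_len(tTarget, length(idx))
  cc <- if (is.null(conditionTarget)) conditionLabel(x)[idx]
        else rep_len(conditionTarget, length(idx))
  e <- .interact(model@params, enc$mu, sinusoidalEncode(tt, model@timeSpec),
                 oneHot(cc, model@conditionLevels))$e
  rownames(e) <- colnames(x)[idx]
  e
}

#' Predict depth-normalized profiles at any time and condition
#'
#' Encodes each query cell (posterior mean), moves it through the
#' temporal interaction layer at the target time and condition, and
#' decodes. For RNA models the result is the per-gene mean fraction
#' (non-negative, rows sum to 1), i.e. the prediction corrects for
#' sequencing depth; for ATAC models it is the per-peak accessibility
#' probability at typical coverage.
#'
#' @inheritParams timeAwareEmbedding
#' @param batchTarget decoding batch (default: each cell's own; for
#'   ATAC models decoded from RNA queries use [predictCrossModality()]).
#' @return cells x features matrix of fractions (RNA) or probabilities
#'   (ATAC).
#' @export
predictProfile <- function(model, x, cells = NULL, tTarget = NULL,
                           conditionTarget = NULL, batchTarget = NULL) {
  dat <- .model_dat(model, x)
  idx <- .cell_idx(x, cells)
  bi <- .batch_input(dat, idx)
  enc <- .encode_batch(model@params, bi, model@latentDim)
  tt <- if (is.null(tTarget)) dat$time[idx] else rep_len(tTarget, length(idx))
  cc <- if (is.null(conditionTarget)) conditionLabel(x)[idx]
        else rep_len(conditionTarget, length(idx))
  bb <- if (is.null(batchTarget)) batchLabel(x)[idx]
        else rep_len(batchTarget, length(idx))
  e <- .interact(model@params, enc$mu, sinusoidalEncode(tt, model@timeSpec),
                 oneHot(cc, model@conditionLevels))$e
  bat <- oneHot(bb, model@batchLevels)
  out <- if (model@modality == "rna") {
    .decode_rna(model@params, e, bat)$frac
  } else {
    covin <- matrix(0, length(idx), 1)
    .decode_atac(model@params, e, bat, covin)$prob
  }
  dimnames(out) <- list(colnames(x)[idx], model@featureIds)
  out
}

#' Model losses on a set of cells
#'
#' `rnaLoss` is the reconstruction/KL objective: mean over cells of the
#' negative ZINB log-likelihood plus the closed-form KL to the
#' standard-normal prior. `discriminatorLoss` is the cross-entropy of
#' the adversarial time discriminator against each cell's time class.
#' `generatorLoss` is their difference (discriminator parameters play
#' no role in its gradient with respect to the generator). All use the
#' posterior mean embedding, so they are deterministic.
#'
#' @inheritParams encodeCells
#' @return a single numeric loss (nats).
#' @export
rnaLoss <- function(model, x, cells = NULL) {
  stopifnot(model@modality == "rna")
  dat <- .model_dat(model, x)
  idx <- .cell_idx(x, cells)
  fw <- .rna_forward(model@params, .batch_input(dat, idx), model@latentDim)
  fw$rec_loss + fw$kl_loss
}

#' @rdname rnaLoss
#' @export
discriminatorLoss <- function(model, x, cells = NULL) {
  dat <- .model_dat(model, x)
  idx <- .cell_idx(x, cells)
  if (anyNA(dat$tclass[idx]))
    stop("cell at a time point unseen during training: no discriminator class")
  bi <- .batch_input(dat, idx)
  enc <- .encode_batch(model@params, bi, model@latentDim)
  .disc_forward_backward(model@params$disc, enc$mu, bi$tclass)$ce
}

#' @rdname rnaLoss
#' @export
generatorLoss <- function(model, x, cells = NULL) {
  rnaLoss(model, x, cells) - discriminatorLoss(model, x, cells)
}
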