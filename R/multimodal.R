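# Coupling of the ATAC-side conditional VAE to the RNA reference model.
# The scATAC-seq model shares the temporal interaction layer with the
# scRNA-seq model (copied and frozen), and its cell embeddings are
# pulled onto the RNA embeddings of coassay partners.

.init_atac_params <- function(P, L, d, nc, nb, inter) {
  h <- .hidden_dim(P, L)
  list(enc = .mlp_init(c(P + d + nc + nb, h, h, 2 * L)),
       inter = inter,
       dec = .mlp_init(c(L + nb, h, h, P)),
       cov_a = 1)
}

.atac_forward <- function(params, bi, L, covin, eps = NULL) {
  enc <- .encode_batch(params, bi, L)
  n <- nrow(enc$mu)
  if (is.null(eps)) eps <- matrix(0, n, L)
  z <- enc$mu + exp(0.5 * enc$lv) * eps
  inter <- .interact(params, z, bi$tenc, bi$con)
  dec <- .decode_atac(params, inter$e, bi$bat, covin)
  ll <- bernoulliLogLik(bi$X, dec$prob)
  kl <- klNormal(enc$mu, enc$lv)
  list(enc = enc, eps = eps, z = z, inter = inter, dec = dec,
       rec_loss = -mean(ll), kl_loss = mean(kl))
}

# Gradients of mean(BCE) + beta * mean(KL) for the ATAC encoder/decoder;
# the shared interaction layer's gradients are computed but the caller
# discards them (frozen per the stepwise schedule).
.atac_backward <- function(params, bi, fw, L, covin, beta = 1,
                           dz_extra = NULL) {
  n <- nrow(fw$z)
  dlogits <- (fw$dec$prob - bi$X) / n
  dcov_a <- sum(dlogits * as.vector(covin))
  bdec <- .mlp_backward(params$dec, fw$dec$A, dlogits)
  dE <- bdec$dX[, seq_len(L), drop = FALSE]
  binter <- .mlp_backward(params$inter, fw$inter$A, dE)
  dz <- binter$dX[, seq_len(L), drop = FALSE]
  if (!is.null(dz_extra)) dz <- dz + dz_extra
  dmu <- dz + beta * fw$enc$mu / n
  dlv <- dz * fw$eps * 0.5 * exp(0.5 * fw$enc$lv) +
    beta * 0.5 * (exp(fw$enc$lv) - 1) / n
  dlv <- dlv * fw$enc$lv_mask
  benc <- .mlp_backward(params$enc, fw$enc$A, cbind(dmu, dlv))
  list(enc = benc$grads, dec = bdec$grads, cov_a = dcov_a)
}

.zero_grads <- function(params) .tree_map(function(p) p * 0, params)

#' Train the coupled RNA + ATAC temporal model
#'
#' Stepwise optimization: step 1 fits the scRNA-seq conditional VAE
#' (via [trainTemporalVAE()], unless a trained `rnaModel` is supplied);
#' step 2 fits the scATAC-seq model with the temporal interaction layer
#' copied from the RNA model and frozen, minimizing the coupled
#' objective: Bernoulli reconstruction + KL, plus `mseWeight` times the
#' mean squared distance between coassay partners' cell embeddings,
#' plus translation losses in both directions (RNA-encoded cells
#' decoded as ATAC and vice versa, scored against the observed partner
#' profile). RNA parameters are not touched in step 2.
#'
#' @param rna,atac [TemporalProfiles-class] objects; every ATAC time
#'   point must also be observed in the RNA data (the reference has the
#'   denser time coverage).
#' @param pairing coassay pairing: a data.frame or TSV path with
#'   columns `rna_cell_id`, `atac_cell_id` (see [readCoassayPairing()]).
#'   Must be non-empty: the alignment is coassay-supervised.
#' @param rnaModel optional pre-trained [TemporalVAE-class] (skips
#'   step 1).
#' @param holdoutTimes ATAC time points excluded from step 2 (test).
#' @param mseWeight embedding-alignment weight lambda (default 100;
#'   grid values 1, 100, 10000).
#' @inheritParams trainTemporalVAE
#' @param rnaArgs list of extra arguments for the step-1
#'   [trainTemporalVAE()] call.
#' @return A [MultimodalVAE-class].
#' @export
trainMultimodal <- function(rna, atac, pairing, rnaModel = NULL,
                            holdoutTimes = numeric(0), mseWeight = 100,
                            latentDim = 50, timeDim = 50, minWavelength = 1,
                            learningRate = 1e-3, batchSize = 128,
                            maxEpochs = 300, patience = 10, klWarmup = 10,
                            seed = 1, verbose = FALSE, rnaArgs = list()) {
  stopifnot(methods::is(rna, "TemporalProfiles"),
            methods::is(atac, "TemporalProfiles"))
  if (modality(atac) != "atac") stop("'atac' must have modality 'atac'")
  pairing <- readCoassayPairing(pairing, rna, atac)
  if (!nrow(pairing))
    stop("coassay pairing is empty: cross-modality alignment requires coassay anchors")
  if (!all(unique(timePoint(atac)) %in% unique(timePoint(rna))))
    stop("every ATAC time point must be observed in the RNA reference")
  if (is.null(rnaModel)) {
    rna_call <- modifyList(
      list(x = rna, latentDim = latentDim, timeDim = timeDim,
           minWavelength = minWavelength, learningRate = learningRate,
           batchSize = batchSize, maxEpochs = maxEpochs,
           patience = patience, klWarmup = klWarmup, seed = seed,
           verbose = verbose),
      rnaArgs)
    rnaModel <- do.call(trainTemporalVAE, rna_call)
  }
  L <- rnaModel@latentDim
  spec <- rnaModel@timeSpec
  set.seed((as.integer(seed) + 1L) %% .Machine$integer.max)
  split <- makeSplit(atac, holdoutTimes, seed = seed)
  conditionLevels <- rnaModel@conditionLevels
  batchLevels <- sort(unique(batchLabel(atac)))
  tr <- match(trainIds(split), colnames(atac))
  va <- match(valIds(split), colnames(atac))
  timeClasses <- sort(unique(timePoint(atac)[tr]))
  depth <- Matrix::colSums(SummarizedExperiment::assay(atac, "counts"))
  depthScale <- median(depth[tr])
  covMean <- mean(log(depth[tr]))
  adat <- .prep_data(atac, spec, conditionLevels, batchLevels,
                     timeClasses, depthScale)
  rdat <- .model_dat(rnaModel, rna)
  P <- nrow(atac)
  params <- .init_atac_params(P, L, spec@d, length(conditionLevels),
                              length(batchLevels), rnaModel@params$inter)
  # frozen RNA-side quantities for the paired cells
  ridx_all <- match(pairing$rna_cell_id, colnames(rna))
  aidx_all <- match(pairing$atac_cell_id, colnames(atac))
  z_rna <- encodeCells(rnaModel, rna)$mean[ridx_all, , drop = FALSE]
  tr_pairs <- which(aidx_all %in% tr)
  va_pairs <- which(aidx_all %in% va)
  upd_group <- c("enc", "dec", "cov_a")
  opt <- .adam_new(params[upd_group])
  best <- list(loss = Inf, params = params, epoch = 0)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  pair_terms <- function(p_sel, want_grads = TRUE, eps_scale = 1) {
    # alignment + both translation losses on the selected pairs
    ri <- ridx_all[p_sel]; ai <- aidx_all[p_sel]
    np <- length(p_sel)
    abi <- .batch_input(adat, ai)
    acov <- matrix(log(abi$depth) - covMean, np, 1)
    aenc <- .encode_batch(params, abi, L)
    zr <- z_rna[p_sel, , drop = FALSE]
    mse <- mean(rowSums((aenc$mu - zr)^2))
    # rna -> atac: frozen RNA embedding decoded as the ATAC partner
    inter_r <- .interact(params, zr, abi$tenc, abi$con)
    dec_r <- .decode_atac(params, inter_r$e, abi$bat, acov)
    t_r2a <- -mean(bernoulliLogLik(abi$X, dec_r$prob))
    # atac -> rna: ATAC embedding decoded through the frozen RNA decoder
    rbi <- .batch_input(rdat, ri)
    inter_a <- .interact(rnaModel@params, aenc$mu, rbi$tenc, rbi$con)
    dec_a <- .decode_rna(rnaModel@params, inter_a$e, rbi$bat)
    theta <- matrix(exp(rnaModel@params$log_theta), np, nrow(rna), byrow = TRUE)
    t_a2r <- -mean(zinbLogLik(rbi$X, rbi$depth * dec_a$frac, theta,
                              plogis(dec_a$droplogit)))
    out <- list(mse = mse, t_r2a = t_r2a, t_a2r = t_a2r)
    if (!want_grads) return(out)
    # gradients wrt ATAC encoder (alignment + atac->rna) and decoder (rna->atac)
    dz_align <- 2 * (aenc$mu - zr) / np
    zg <- .zinb_grads(rbi$X, rbi$depth * dec_a$frac, theta, dec_a$droplogit)
    dLmu <- -zg$dmu / np
    rs <- rowSums(dLmu * dec_a$frac)
    dS <- rbi$depth * dec_a$frac * (dLmu - rs)
    dGL <- -zg$dlogit / np
    bdec_r <- .mlp_backward(rnaModel@params$dec, dec_a$A, cbind(dS, dGL))
    binter_a <- .mlp_backward(rnaModel@params$inter, inter_a$A,
                              bdec_r$dX[, seq_len(L), drop = FALSE])
    dz_trans <- binter_a$dX[, seq_len(L), drop = FALSE]
    dmu <- mseWeight * dz_align + dz_trans
    benc <- .mlp_backward(params$enc, aenc$A,
                          cbind(dmu, matrix(0, np, L)))
    dlog_r <- (dec_r$prob - abi$X) / np
    bdec <- .mlp_backward(params$dec, dec_r$A, dlog_r)
    out$grads <- list(enc = benc$grads, dec = bdec$grads,
                      cov_a = sum(dlog_r * as.vector(acov)))
    out
  }
  val_loss <- function() {
    if (!length(va)) return(NA_real_)
    abi <- .batch_input(adat, va)
    acov <- matrix(log(abi$depth) - covMean, length(va), 1)
    fw <- .atac_forward(params, abi, L, acov)
    v <- fw$rec_loss + fw$kl_loss
    if (length(va_pairs)) {
      pt <- pair_terms(va_pairs, want_grads = FALSE)
      v <- v + mseWeight * pt$mse + pt$t_r2a + pt$t_a2r
    }
    v
  }
  for (epoch in seq_len(maxEpochs)) {
    beta <- if (klWarmup > 0) min(1, epoch / klWarmup) else 1
    ord <- sample(tr)
    nb_batches <- ceiling(length(ord) / batchSize)
    ep_loss <- 0
    for (b in seq_len(nb_batches)) {
      idx <- ord[((b - 1) * batchSize + 1):min(b * batchSize, length(ord))]
      n <- length(idx)
      bi <- .batch_input(adat, idx)
      covin <- matrix(log(bi$depth) - covMean, n, 1)
      eps <- matrix(rnorm(n * L), n, L)
      fw <- .atac_forward(params, bi, L, covin, eps)
      grads <- .atac_backward(params, bi, fw, L, covin, beta)
      step_loss <- fw$rec_loss + beta * fw$kl_loss
      if (length(tr_pairs)) {
        p_sel <- if (length(tr_pairs) > n) sample(tr_pairs, n) else tr_pairs
        pt <- pair_terms(p_sel)
        grads <- .tree_add(grads, pt$grads)
        step_loss <- step_loss + mseWeight * pt$mse + pt$t_r2a + pt$t_a2r
      }
      up <- .adam_step(params[upd_group], grads, opt, learningRate)
      params[upd_group] <- up$params; opt <- up$state
      ep_loss <- ep_loss + step_loss * n
    }
    ep_loss <- ep_loss / length(ord)
    vl <- val_loss()
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("atac epoch %3d | train %.3f | val %.3f",
                      epoch, ep_loss, vl))
    if (is.finite(vl) && vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  atacModel <- methods::new("TemporalVAE", modality = "atac",
    featureIds = rownames(atac), latentDim = as.numeric(L), timeSpec = spec,
    conditionLevels = conditionLevels, batchLevels = batchLevels,
    timeClasses = timeClasses, params = best$params,
    config = list(depthScale = depthScale, covMean = covMean,
                  learningRate = learningRate, batchSize = batchSize,
                  klWarmup = klWarmup, mseWeight = mseWeight,
                  patience = patience, maxEpochs = maxEpochs, seed = seed),
    history = hist, seed = as.numeric(seed))
  methods::new("MultimodalVAE", rna = rnaModel, atac = atacModel,
               mseWeight = mseWeight, pairing = pairing)
}

#' Bernoulli reconstruction + KL loss for an ATAC model
#'
#' Mean over cells of the binary cross-entropy of the reconstructed
#' accessibility probabilities plus the KL to the standard-normal
#' prior, at the posterior-mean embedding.
#'
#' @param model an ATAC [TemporalVAE-class].
#' @param x a [TemporalProfiles-class] with modality `"atac"`.
#' @param cells optional cell ids or indices.
#' @return numeric loss (nats).
#' @export
atacLoss <- function(model, x, cells = NULL) {
  stopifnot(model@modality == "atac")
  if (modality(x) != "atac") stop("atacLoss requires binarized ATAC input")
  dat <- .model_dat(model, x)
  idx <- .cell_idx(x, cells)
  bi <- .batch_input(dat, idx)
  covin <- matrix(log(bi$depth) - model@config$covMean, length(idx), 1)
  fw <- .atac_forward(model@params, bi, model@latentDim, covin)
  fw$rec_loss + fw$kl_loss
}

#' Mean squared distance between paired cell embeddings
#'
#' The coassay alignment loss: mean over pairs of the squared Euclidean
#' distance between corresponding rows. With a `pairing`, rows are
#' looked up by the id columns; otherwise rows are matched by position.
#'
#' @param rnaEmb,atacEmb numeric matrices (cells x L), with rownames
#'   when `pairing` is used.
#' @param pairing optional data.frame with `rna_cell_id`, `atac_cell_id`.
#' @return numeric loss.
#' @export
alignmentLoss <- function(rnaEmb, atacEmb, pairing = NULL) {
  if (!is.null(pairing)) {
    ri <- match(pairing$rna_cell_id, rownames(rnaEmb))
    ai <- match(pairing$atac_cell_id, rownames(atacEmb))
    if (anyNA(ri) || anyNA(ai)) stop("pairing refers to unknown cell id(s)")
    rnaEmb <- rnaEmb[ri, , drop = FALSE]
    atacEmb <- atacEmb[ai, , drop = FALSE]
  }
  if (!all(dim(rnaEmb) == dim(atacEmb)))
    stop("embeddings must have matching dimensions")
  mean(rowSums((rnaEmb - atacEmb)^2))
}

#' Cross-modality translation loss on coassay pairs
#'
#' Encodes each pair's source-modality cell, decodes it in the target
#' modality through the shared temporal interaction layer, and scores
#' the observed target profile under the decoder's likelihood
#' (Bernoulli for `rna2atac`, ZINB for `atac2rna`). Returns the mean
#' negative log-likelihood per cell.
#'
#' @param mm a [MultimodalVAE-class].
#' @param rna,atac the [TemporalProfiles-class] objects.
#' @param pairing optional pairing (default: the one stored in `mm`).
#' @param direction `"rna2atac"` or `"atac2rna"`.
#' @return numeric loss (nats).
#' @export
translationLoss <- function(mm, rna, atac, pairing = NULL,
                            direction = c("rna2atac", "atac2rna")) {
  direction <- match.arg(direction)
  if (is.null(pairing)) pairing <- mm@pairing
  pairing <- readCoassayPairing(pairing, rna, atac)
  if (!nrow(pairing)) stop("translation loss needs a non-empty pairing")
  ri <- match(pairing$rna_cell_id, colnames(rna))
  ai <- match(pairing$atac_cell_id, colnames(atac))
  L <- mm@rna@latentDim
  adat <- .model_dat(mm@atac, atac)
  rdat <- .model_dat(mm@rna, rna)
  abi <- .batch_input(adat, ai)
  rbi <- .batch_input(rdat, ri)
  if (direction == "rna2atac") {
    z <- encodeCells(mm@rna, rna, pairing$rna_cell_id)$mean
    inter <- .interact(mm@atac@params, z, abi$tenc, abi$con)
    acov <- matrix(log(abi$depth) - mm@atac@config$covMean, length(ai), 1)
    dec <- .decode_atac(mm@atac@params, inter$e, abi$bat, acov)
    -mean(bernoulliLogLik(abi$X, dec$prob))
  } else {
    z <- encodeCells(mm@atac, atac, pairing$atac_cell_id)$mean
    inter <- .interact(mm@rna@params, z, rbi$tenc, rbi$con)
    dec <- .decode_rna(mm@rna@params, inter$e, rbi$bat)
    theta <- matrix(exp(mm@rna@params$log_theta), length(ri), nrow(rna),
                    byrow = TRUE)
    -mean(zinbLogLik(rbi$X, rbi$depth * dec$frac, theta,
                     plogis(dec$droplogit)))
  }
}

#' Coupled multimodal objective
#'
#' `atacLoss + lambda * alignmentLoss + translationLoss(rna2atac) +
#'  translationLoss(atac2rna)` evaluated on the given cells and pairs.
#'
#' @inheritParams translationLoss
#' @param cells optional ATAC cell subset for the reconstruction term.
#' @param mseWeight lambda; defaults to the weight stored in `mm`.
#' @return numeric loss (nats).
#' @export
multimodalLoss <- function(mm, rna, atac, pairing = NULL, cells = NULL,
                           mseWeight = NULL) {
  if (is.null(pairing)) pairing <- mm@pairing
  if (is.null(mseWeight)) mseWeight <- mm@mseWeight
  ze_r <- encodeCells(mm@rna, rna)$mean
  ze_a <- encodeCells(mm@atac, atac)$mean
  atacLoss(mm@atac, atac, cells) +
    mseWeight * alignmentLoss(ze_r, ze_a, pairing) +
    translationLoss(mm, rna, atac, pairing, "rna2atac") +
    translationLoss(mm, rna, atac, pairing, "atac2rna")
}

#' Predict chromatin accessibility from RNA queries
#'
#' Encodes scRNA-seq query cells with the RNA encoder, moves them
#' through the shared temporal interaction layer at the target time,
#' and decodes peak probabilities with the ATAC decoder (at typical
#' coverage, in the reference ATAC batch). Entries lie in (0, 1) and
#' vary continuously with `tTarget`.
#'
#' @param mm a [MultimodalVAE-class].
#' @param rna a [TemporalProfiles-class] with the RNA model's features.
#' @param cells optional query cell ids or indices.
#' @param tTarget target time(s) in days (default: each cell's own).
#' @param conditionTarget target condition (default: each cell's own).
#' @return cells x peaks matrix of accessibility probabilities.
#' @export
predictCrossModality <- function(mm, rna, cells = NULL, tTarget = NULL,
                                 conditionTarget = NULL) {
  if (!length(mm@atac@params)) stop("ATAC decoder has not been trained")
  dat <- .model_dat(mm@rna, rna)
  idx <- .cell_idx(rna, cells)
  bi <- .batch_input(dat, idx)
  enc <- .encode_batch(mm@rna@params, bi, mm@rna@latentDim)
  tt <- if (is.null(tTarget)) dat$time[idx] else rep_len(tTarget, length(idx))
  cc <- if (is.null(conditionTarget)) conditionLabel(rna)[idx]
        else rep_len(conditionTarget, length(idx))
  e <- .interact(mm@atac@params, enc$mu,
                 sinusoidalEncode(tt, mm@atac@timeSpec),
                 oneHot(cc, mm@atac@conditionLevels))$e
  bat <- oneHot(rep(mm@atac@batchLevels[1], length(idx)),
                mm@atac@batchLevels)
  prob <- .decode_atac(mm@atac@params, e, bat,
                       matrix(0, length(idx), 1))$prob
  dimnames(prob) <- list(colnames(rna)[idx], mm@atac@featureIds)
  prob
}
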