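# Reverse-mode gradients for the encoder and task heads, plus the Adam
# optimizer. The layer-norm, softmax-attention and GELU derivatives here
# are checked against central-difference numerical gradients in the tests.

rowmat <- function(v, M) matrix(v, nrow(M), ncol(M), byrow = TRUE)

# Layer-norm backward for population-variance normalization; dy is the
# gradient at the output, xhat/istd come from the forward cache.
ln_backward <- function(dy, xhat, istd, g) {
  dxhat <- dy * rowmat(g, dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = (dxhat - m1 - xhat * m2) * istd,
       dg = colSums(dy * xhat),
       db = colSums(dy))
}

acc <- function(grads, name, val) {
  grads[[name]] <- if (is.null(grads[[name]])) val else grads[[name]] + val
  grads
}

# Backward through the encoder stack. `dH` is the gradient at the final
# hidden states (flat (B*L) x d). Returns gradients for every encoder
# parameter including the embeddings.
encoder_backward <- function(params, cfg, cache, dH) {
  nh <- cfg$n_heads; d <- cfg$d_model
  B <- cache$B; L <- cache$L
  grads <- list()
  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    cl <- cache$layers[[l]]
    g2 <- params[[pname(l, "ln2_g")]]
    lb <- ln_backward(dX, cl$xhat2, cl$istd2, g2)
    grads <- acc(grads, pname(l, "ln2_g"), lb$dg)
    grads <- acc(grads, pname(l, "ln2_b"), lb$db)
    dR2 <- lb$dx
    dX1 <- dR2
    dF2 <- if (is.null(cl$drop2)) dR2 else dR2 * cl$drop2
    grads <- acc(grads, pname(l, "W2"), crossprod(cl$G, dF2))
    grads <- acc(grads, pname(l, "b2"), colSums(dF2))
    dG <- dF2 %*% t(params[[pname(l, "W2")]])
    dF1 <- dG * gelu_grad(cl$F1)
    grads <- acc(grads, pname(l, "W1"), crossprod(cl$X1, dF1))
    grads <- acc(grads, pname(l, "b1"), colSums(dF1))
    dX1 <- dX1 + dF1 %*% t(params[[pname(l, "W1")]])
    g1 <- params[[pname(l, "ln1_g")]]
    lb1 <- ln_backward(dX1, cl$xhat1, cl$istd1, g1)
    grads <- acc(grads, pname(l, "ln1_g"), lb1$dg)
    grads <- acc(grads, pname(l, "ln1_b"), lb1$db)
    dR1 <- lb1$dx
    dX_in <- dR1
    dP <- if (is.null(cl$drop1)) dR1 else dR1 * cl$drop1
    grads <- acc(grads, pname(l, "Wo"), crossprod(cl$O, dP))
    grads <- acc(grads, pname(l, "bo"), colSums(dP))
    dO <- dP %*% t(params[[pname(l, "Wo")]])
    ab <- .attn_backward(dO, cl$A, cl$Qc, cl$Kc, cl$Vc, B, L, nh)
    dQc <- ab$dQ; dKc <- ab$dK; dVc <- ab$dV
    grads <- acc(grads, pname(l, "Wq"), crossprod(cl$X_in, dQc))
    grads <- acc(grads, pname(l, "bq"), colSums(dQc))
    grads <- acc(grads, pname(l, "Wk"), crossprod(cl$X_in, dKc))
    grads <- acc(grads, pname(l, "bk"), colSums(dKc))
    grads <- acc(grads, pname(l, "Wv"), crossprod(cl$X_in, dVc))
    grads <- acc(grads, pname(l, "bv"), colSums(dVc))
    dX_in <- dX_in + dQc %*% t(params[[pname(l, "Wq")]]) +
      dKc %*% t(params[[pname(l, "Wk")]]) +
      dVc %*% t(params[[pname(l, "Wv")]])
    dX <- dX_in
  }
  dtok <- matrix(0, nrow(params$tok_emb), d)
  rs <- rowsum(dX, cache$ids_flat)
  dtok[as.integer(rownames(rs)) + 1L, ] <- rs
  grads <- acc(grads, "tok_emb", dtok)
  dseg <- matrix(0, 2L, d)
  rs2 <- rowsum(dX, cache$seg_flat)
  dseg[as.integer(rownames(rs2)) + 1L, ] <- rs2
  grads <- acc(grads, "seg_emb", dseg)
  grads
}

# One pre-training forward/backward on a batch of masked extent pairs.
# instances: list of masked_instance; labels: binary NCP labels.
pretrain_step <- function(params, cfg, instances, labels, train = TRUE) {
  bt <- build_batch(instances)
  B <- nrow(bt$ids); L <- ncol(bt$ids)
  fwd <- encoder_forward(params, cfg, bt$ids, bt$seg, bt$pad,
                         train = train, keep = TRUE)
  H <- fwd$hidden
  # masked-position rows in the flat layout
  mrows <- integer(0); targets <- integer(0)
  for (b in seq_len(B)) {
    mp <- instances[[b]]$masked_positions
    mrows <- c(mrows, (b - 1L) * L + mp)
    targets <- c(targets, instances[[b]]$target_ids)
  }
  M <- length(mrows)
  Hm <- H[mrows, , drop = FALSE]
  Wout <- if (cfg$tie_mtp) t(params$tok_emb) else params$mtp_W
  logits <- add_bias(Hm %*% Wout, params$mtp_b)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(M), targets + 1L)]
  loss_mtp <- mean(-log(pmax(picked, 1e-300)))
  cls <- fwd$cls
  s <- as.vector(cls %*% params$ncp_w + params$ncp_b)
  prob <- sigmoid(s)
  loss_ncp <- bce_from_logits(s, labels)
  loss <- loss_mtp + loss_ncp

  # backward: MTP
  dlogits <- P
  dlogits[cbind(seq_len(M), targets + 1L)] <-
    dlogits[cbind(seq_len(M), targets + 1L)] - 1
  dlogits <- dlogits / M
  grads <- list()
  grads$mtp_b <- colSums(dlogits)
  dHm <- dlogits %*% t(Wout)
  if (cfg$tie_mtp) {
    grads$tok_emb <- crossprod(dlogits, Hm)   # logits = Hm %*% t(tok_emb)
  } else {
    grads$mtp_W <- crossprod(Hm, dlogits)
  }
  # backward: NCP
  ds <- (prob - labels) / B
  grads$ncp_w <- crossprod(cls, ds)
  grads$ncp_b <- sum(ds)
  dcls <- ds %*% t(params$ncp_w)
  dH <- matrix(0, B * L, cfg$d_model)
  dH[mrows, ] <- dH[mrows, , drop = FALSE] + dHm
  cls_rows <- (seq_len(B) - 1L) * L + 1L
  dH[cls_rows, ] <- dH[cls_rows, , drop = FALSE] + dcls
  enc <- encoder_backward(params, cfg, fwd$cache, dH)
  for (nm in names(enc)) grads <- acc(grads, nm, enc[[nm]])
  list(loss = loss, loss_mtp = loss_mtp, loss_ncp = loss_ncp,
       prob = prob, grads = grads)
}

# One fine-tuning forward/backward for the object-object head.
oo_step <- function(params, cfg, sequences, labels, train = TRUE) {
  bt <- build_batch(sequences)
  B <- nrow(bt$ids); L <- ncol(bt$ids)
  fwd <- encoder_forward(params, cfg, bt$ids, bt$seg, bt$pad,
                         train = train, keep = TRUE)
  cls <- fwd$cls
  z <- cls %*% params$oo_Wcls
  r <- pmax(z, 0)
  s <- as.vector(r %*% params$oo_Wout)
  prob <- sigmoid(s)
  loss <- bce_from_logits(s, labels)
  ds <- (prob - labels) / B
  grads <- list(oo_Wout = crossprod(r, ds))
  dr <- ds %*% t(params$oo_Wout)
  dz <- dr * (z > 0)
  grads$oo_Wcls <- crossprod(cls, dz)
  dcls <- dz %*% t(params$oo_Wcls)
  dH <- matrix(0, B * L, cfg$d_model)
  cls_rows <- (seq_len(B) - 1L) * L + 1L
  dH[cls_rows, ] <- dcls
  enc <- encoder_backward(params, cfg, fwd$cache, dH)
  for (nm in names(enc)) grads <- acc(grads, nm, enc[[nm]])
  list(loss = loss, prob = prob, grads = grads)
}

# One fine-tuning forward/backward for the two-tower object-attribute head.
# The oa head weights live in `obj_params`; both towers receive gradients.
oa_step <- function(obj_params, att_params, cfg_obj, cfg_att,
                    obj_sequences, att_sequences, labels, train = TRUE) {
  bo <- build_batch(obj_sequences)
  ba <- build_batch(att_sequences)
  B <- nrow(bo$ids)
  f1 <- encoder_forward(obj_params, cfg_obj, bo$ids, bo$seg, bo$pad,
                        train = train, keep = TRUE)
  f2 <- encoder_forward(att_params, cfg_att, ba$ids, ba$seg, ba$pad,
                        train = train, keep = TRUE)
  cat_cls <- cbind(f1$cls, f2$cls)
  z <- cat_cls %*% obj_params$oa_Wcls
  r <- pmax(z, 0)
  s <- as.vector(r %*% obj_params$oa_Wout)
  prob <- sigmoid(s)
  loss <- bce_from_logits(s, labels)
  ds <- (prob - labels) / B
  g_obj <- list(oa_Wout = crossprod(r, ds))
  dr <- ds %*% t(obj_params$oa_Wout)
  dz <- dr * (z > 0)
  g_obj$oa_Wcls <- crossprod(cat_cls, dz)
  dcat <- dz %*% t(obj_params$oa_Wcls)
  d1 <- dcat[, seq_len(cfg_obj$d_model), drop = FALSE]
  d2 <- dcat[, cfg_obj$d_model + seq_len(cfg_att$d_model), drop = FALSE]
  mk_dH <- function(B, L, d, dcls) {
    dH <- matrix(0, B * L, d)
    dH[(seq_len(B) - 1L) * L + 1L, ] <- dcls
    dH
  }
  e1 <- encoder_backward(obj_params, cfg_obj, f1$cache,
                         mk_dH(B, ncol(bo$ids), cfg_obj$d_model, d1))
  for (nm in names(e1)) g_obj <- acc(g_obj, nm, e1[[nm]])
  g_att <- encoder_backward(att_params, cfg_att, f2$cache,
                            mk_dH(B, ncol(ba$ids), cfg_att$d_model, d2))
  list(loss = loss, prob = prob, grads_obj = g_obj, grads_att = g_att)
}

# ---- Adam ------------------------------------------------------------

adam_init <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- mhat / (sqrt(vhat) + eps)
    # decoupled weight decay on weight matrices only (not gains/biases)
    if (weight_decay > 0 && grepl("W|emb", nm)) {
      step <- step + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}
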