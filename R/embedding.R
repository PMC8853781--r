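#' Training configuration for the complex-valued embedding model
#'
#' The source method names ComplEx as its embedding model but publishes no
#' hyperparameters; these defaults are the package's own and every one is
#' overridable.  Dimensions of entity and relation embeddings coincide
#' (`d`), as they must for the Hermitian three-way product.
#'
#' @param d Embedding dimension (complex components per vector).
#' @param epochs Number of passes over the triple set.
#' @param lr Learning rate (for AdaGrad this is the base step size).
#' @param negatives Corrupted triples sampled per positive.
#' @param reg L2 regularisation weight applied to minibatch rows.
#' @param batch_size Positives per minibatch.
#' @param init_sd Gaussian s.d. for real and imaginary initialisation.
#' @param optimizer `"adagrad"` (per-coordinate adaptive steps; robust to
#'   the uneven update frequency of hub entities such as syndromes) or
#'   `"sgd"` (fixed step).
#' @param seed RNG seed; recorded in the result for reproducibility.
#' @return A `train_config` list.
#' @export
train_config <- function(d = 100L, epochs = 200L, lr = 0.05, negatives = 20L,
                         reg = 1e-3, batch_size = 512L, init_sd = 0.1,
                         optimizer = c("adagrad", "sgd"), seed = 1L) {
  cfg <- list(d = as.integer(d), epochs = as.integer(epochs), lr = lr,
              negatives = as.integer(negatives), reg = reg,
              batch_size = as.integer(batch_size), init_sd = init_sd,
              optimizer = match.arg(optimizer), seed = as.integer(seed))
  stopifnot(cfg$d >= 1L, cfg$epochs >= 0L, cfg$lr > 0, cfg$negatives >= 1L,
            cfg$reg >= 0, cfg$batch_size >= 1L, cfg$init_sd > 0)
  structure(cfg, class = "train_config")
}

new_complex_embeddings <- function(entities, relations, config) {
  stopifnot(is.complex(entities), is.complex(relations),
            ncol(entities) == ncol(relations))
  structure(list(entities = entities, relations = relations,
                 d = ncol(entities), config = config),
            class = "complex_embeddings")
}

#' @export
print.complex_embeddings <- function(x, ...) {
  cat("<complex_embeddings> ", nrow(x$entities), " entities x ",
      nrow(x$relations), " relations, d = ", x$d, "\n", sep = "")
  invisible(x)
}

init_embeddings <- function(n_entities, n_relations, config) {
  set.seed(config$seed)
  d <- config$d
  rmat <- function(n) matrix(
    complex(real = stats::rnorm(n * d, 0, config$init_sd),
            imaginary = stats::rnorm(n * d, 0, config$init_sd)),
    nrow = n, ncol = d)
  new_complex_embeddings(rmat(n_entities), rmat(n_relations), config)
}

#' Score a triple with the Hermitian three-way product
#'
#' The ComplEx scoring function
#' \deqn{\phi(h, l, t) = \mathrm{Re}\sum_{k=1}^{d} e_h[k]\, e_l[k]\,
#'   \overline{e_t}[k],}
#' the real part of the component-wise product of head, relation and the
#' complex conjugate of the tail.  A relation with a purely real vector
#' scores symmetrically (`phi(h,l,t) == phi(t,l,h)`); a purely imaginary
#' one antisymmetrically.
#'
#' @param h,l,t Integer ids into the entity / relation tables.
#' @param emb A `complex_embeddings` object.
#' @return Real scalar score (vectorised over equal-length id vectors).
#' @export
score_triple <- function(h, l, t, emb) {
  stopifnot(inherits(emb, "complex_embeddings"))
  ids_ok <- function(i, n) all(i >= 1L & i <= n) && !anyNA(i)
  if (!ids_ok(h, nrow(emb$entities)) || !ids_ok(t, nrow(emb$entities)))
    stop("entity id out of range")
  if (!ids_ok(l, nrow(emb$relations)))
    stop("relation id out of range")
  H <- emb$entities[h, , drop = FALSE]
  L <- emb$relations[l, , drop = FALSE]
  T_ <- emb$entities[t, , drop = FALSE]
  unname(rowSums(Re(H * L * Conj(T_))))
}

# entity ids grouped by type, for type-aware corruption
entity_type_pools <- function(kg) {
  split(kg$entities$id, kg$entities$etype)
}

relation_tail_type <- function(kg) {
  rel <- kg$relations
  ifelse(rel$kind == "method_performance", rel$field_type, "syndrome")
}

#' Sample corrupted triples for a positive
#'
#' Replaces the head and/or tail of `triple` with entities drawn uniformly
#' from the same entity type as the replaced slot (type-aware corruption:
#' syndrome relations corrupt within syndrome entities).  Under
#' `filtered = TRUE` no corruption may itself be a known triple of `kg`.
#'
#' @param triple Integer vector `c(h, l, t)`.
#' @param kg A `dsds_kg` (vocabulary and, for filtering, the triple set).
#' @param count Number of corruptions.
#' @param mode Which slot to corrupt: `"tail"`, `"head"` or `"both"`.
#' @param filtered Exclude corruptions that are themselves true triples.
#' @return Data frame with columns `h`, `l`, `t` (`count` rows).
#' @export
sample_negatives <- function(triple, kg, count, mode = c("tail", "head", "both"),
                             filtered = FALSE) {
  mode <- match.arg(mode)
  stopifnot(count >= 1L, length(triple) == 3L)
  pools <- entity_type_pools(kg)
  ttype <- relation_tail_type(kg)
  etype_of <- setNames(kg$entities$etype, kg$entities$id)
  slot_pool <- function(slot) {
    ty <- if (slot == "t") ttype[match(triple[2L], kg$relations$id)]
          else etype_of[[as.character(triple[1L])]]
    pool <- setdiff(pools[[ty]], triple[if (slot == "t") 3L else 1L])
    if (length(pool) < 1L)
      stop("no valid corruption: fewer than 2 entities of type '", ty, "'")
    pool
  }
  known <- if (filtered) kg_triple_keys(kg) else character(0)
  draw_one <- function() {
    for (attempt in seq_len(1000L)) {
      slot <- switch(mode, tail = "t", head = "h",
                     both = sample(c("h", "t"), 1L))
      cand <- triple
      pool <- slot_pool(slot)
      cand[if (slot == "t") 3L else 1L] <-
        pool[sample.int(length(pool), 1L)]
      key <- paste(cand[1L], cand[2L], cand[3L], sep = "_")
      if (!filtered || !(key %in% known)) return(cand)
    }
    stop("no valid corruption exists for triple (",
         paste(triple, collapse = ", "), ")")
  }
  out <- t(vapply(seq_len(count), function(i) draw_one(), integer(3L)))
  data.frame(h = out[, 1L], l = out[, 2L], t = out[, 3L])
}

# scatter-add complex rows: base rowsum() handles only numeric, so real and
# imaginary planes are accumulated separately
rowsum_complex <- function(m, idx) {
  re <- rowsum(Re(m), idx)
  im <- rowsum(Im(m), idx)
  list(ids = as.integer(rownames(re)), g = re + 1i * im)
}

#' Train complex-valued embeddings on a knowledge graph
#'
#' Minimises a pointwise logistic loss, `log(1 + exp(-y * phi))` with
#' `y = +1` for graph triples and `y = -1` for sampled corruptions, by
#' minibatch gradient descent (AdaGrad by default) with L2 regularisation
#' on the rows touched by each batch.  Corruptions replace the tail with a
#' uniformly drawn entity of the relation's legal tail type (unfiltered:
#' standard training practice).  Fully deterministic given the config seed.
#'
#' @param kg A non-empty `dsds_kg`.
#' @param config A [train_config()].
#' @param verbose Print the loss every 25 epochs.
#' @return A `complex_embeddings` with attribute `loss` (per-epoch mean
#'   logistic loss) and the config stored inside.
#' @export
train_model <- function(kg, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(kg, "dsds_kg"))
  ntri <- nrow(kg$triples)
  if (ntri == 0L) stop("knowledge graph has no triples")
  emb <- init_embeddings(nrow(kg$entities), nrow(kg$relations), config)
  E <- emb$entities; R <- emb$relations
  d <- config$d; nneg <- config$negatives

  # per-relation tail pools for type-aware corruption
  ttype <- relation_tail_type(kg)
  pools <- entity_type_pools(kg)
  tail_pool <- lapply(seq_len(nrow(kg$relations)), function(i) pools[[ttype[i]]])

  hs <- kg$triples$h; ls <- kg$triples$l; ts <- kg$triples$t
  losses <- numeric(config$epochs)
  if (config$epochs == 0L) return(emb)
  adagrad <- config$optimizer == "adagrad"
  if (adagrad) {   # squared-gradient accumulators, real and imaginary planes
    GEr <- GEi <- matrix(0, nrow(E), d)
    GRr <- GRi <- matrix(0, nrow(R), d)
    eps <- 1e-8
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(ntri)
    starts <- seq(1L, ntri, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, ntri)]
      bh <- hs[idx]; bl <- ls[idx]; bt <- ts[idx]
      nb <- length(idx)
      # tail corruptions, nneg per positive, drawn within the tail type
      nh <- rep(bh, each = nneg)
      nl <- rep(bl, each = nneg)
      nt <- integer(nb * nneg)
      for (rl in unique(nl)) {        # pools depend only on the relation
        sel <- which(nl == rl)
        pool <- tail_pool[[rl]]
        nt[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
      }
      # a corruption equal to the positive triple is no corruption; redraw
      # (bounded: tiny tail pools could otherwise loop forever)
      true_t <- rep(bt, each = nneg)
      for (round in seq_len(10L)) {
        clash <- which(nt == true_t)
        if (!length(clash)) break
        for (rl in unique(nl[clash])) {
          sel <- clash[nl[clash] == rl]
          pool <- tail_pool[[rl]]
          if (length(pool) < 2L) next
          nt[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
        }
      }
      ah <- c(bh, nh); al <- c(bl, nl); at <- c(bt, nt)
      y <- c(rep(1, nb), rep(-1, nb * nneg))

      H <- E[ah, , drop = FALSE]; L <- R[al, , drop = FALSE]
      T_ <- E[at, , drop = FALSE]
      phi <- rowSums(Re(H * L * Conj(T_)))
      z <- y * phi
      ep_loss <- ep_loss + sum(log1p(exp(-abs(z))) + pmax(-z, 0))
      if (!is.finite(ep_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      w <- -y / (1 + exp(z))        # d loss / d phi
      gH <- w * (Conj(L) * T_) + config$reg * H
      gL <- w * (Conj(H) * T_) + config$reg * L
      gT <- w * (H * L) + config$reg * T_

      accE <- rowsum_complex(rbind(gH, gT), c(ah, at))
      accR <- rowsum_complex(gL, al)
      if (adagrad) {
        ie <- accE$ids; ir <- accR$ids
        GEr[ie, ] <- GEr[ie, , drop = FALSE] + Re(accE$g)^2
        GEi[ie, ] <- GEi[ie, , drop = FALSE] + Im(accE$g)^2
        GRr[ir, ] <- GRr[ir, , drop = FALSE] + Re(accR$g)^2
        GRi[ir, ] <- GRi[ir, , drop = FALSE] + Im(accR$g)^2
        stepE <- config$lr * (Re(accE$g) / sqrt(GEr[ie, , drop = FALSE] + eps) +
                              1i * Im(accE$g) / sqrt(GEi[ie, , drop = FALSE] + eps))
        stepR <- config$lr * (Re(accR$g) / sqrt(GRr[ir, , drop = FALSE] + eps) +
                              1i * Im(accR$g) / sqrt(GRi[ir, , drop = FALSE] + eps))
        E[ie, ] <- E[ie, , drop = FALSE] - stepE
        R[ir, ] <- R[ir, , drop = FALSE] - stepR
      } else {
        E[accE$ids, ] <- E[accE$ids, , drop = FALSE] - config$lr * accE$g
        R[accR$ids, ] <- R[accR$ids, , drop = FALSE] - config$lr * accR$g
      }
    }
    losses[epoch] <- ep_loss / (ntri * (1 + nneg))
    if (verbose && epoch %% 25L == 0L)
      message("epoch ", epoch, ": loss ", format(losses[epoch], digits = 5))
  }
  out <- new_complex_embeddings(E, R, config)
  attr(out, "loss") <- losses
  out
}

#' Rank candidate tail entities for a query
#'
#' Scores every candidate tail for the query `(h, l, ?)` and returns them
#' sorted by descending score; ties are broken by ascending entity id, so
#' the order is fully deterministic.
#'
#' @param h Head entity id.
#' @param l Relation id.
#' @param candidates Non-empty integer vector of candidate entity ids.
#' @param emb A `complex_embeddings`.
#' @return Data frame with columns `candidate`, `score`, in rank order.
#' @export
rank_candidates <- function(h, l, candidates, emb) {
  if (!length(candidates)) stop("empty candidate list")
  sc <- score_triple(rep(h, length(candidates)), rep(l, length(candidates)),
                     candidates, emb)
  ord <- order(-sc, candidates)
  data.frame(candidate = candidates[ord], score = sc[ord])
}

# checkpoint I/O ------------------------------------------------------------

#' Save and load an embedding checkpoint as plain text
#'
#' The checkpoint directory holds the real and imaginary planes of the
#' entity and relation tables as TSV matrices plus the training config as
#' JSON.  `load_checkpoint(save_checkpoint(emb, dir))` restores the
#' embeddings bit-exactly (values are serialised at full precision).
#'
#' @param emb A `complex_embeddings`.
#' @param dir Checkpoint directory (created if missing).
#' @return `save_checkpoint()`: `dir` invisibly; `load_checkpoint()`: a
#'   `complex_embeddings`.
#' @export
save_checkpoint <- function(emb, dir) {
  stopifnot(inherits(emb, "complex_embeddings"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) utils::write.table(
    format(m, digits = 17, scientific = TRUE, trim = TRUE),
    file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  wm(Re(emb$entities), "entities_re.tsv")
  wm(Im(emb$entities), "entities_im.tsv")
  wm(Re(emb$relations), "relations_re.tsv")
  wm(Im(emb$relations), "relations_im.tsv")
  jsonlite::write_json(unclass(emb$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  rm_ <- function(f) as.matrix(utils::read.table(
    file.path(dir, f), sep = "\t", header = FALSE))
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg <- do.call(train_config, cfg)
  ent <- rm_("entities_re.tsv") + 1i * rm_("entities_im.tsv")
  rel <- rm_("relations_re.tsv") + 1i * rm_("relations_im.tsv")
  dimnames(ent) <- dimnames(rel) <- NULL
  new_complex_embeddings(ent, rel, cfg)
}
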