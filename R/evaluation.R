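## Accuracy evaluation: a ranked candidate is correct iff the identical
## canonical word was among the SSWs answered for that image.

#' Answered SSW sets per image
#'
#' @param annotations Long data frame \code{image_id}, \code{ssw}.
#' @return Named list: canonical SSW types answered for each image.
#' @export
answeredSets <- function(annotations) {
  canon <- canonicalSSW(annotations$ssw)
  lapply(split(canon, annotations$image_id), unique)
}

#' Fraction of images whose rank-th candidate was answered
#'
#' Correctness is canonical-romanization string membership in the image's
#' answered set, mirroring the evaluation rule of the reference experiment.
#'
#' @param ranked Named list (by image id) of candidate character vectors in
#'   ascending-loss order, or the results data frame of [evaluateModel()].
#' @param answered Named list of answered SSW sets (see [answeredSets()]).
#' @param rank Candidate rank to score, 1-based.
#' @return Accuracy fraction in [0,1].
#' @export
candidateAccuracy <- function(ranked, answered, rank = 1L) {
  if (is.data.frame(ranked)) {
    ranked <- ranked[order(ranked$image_id, ranked$rank), ]
    ranked <- split(ranked$candidate, ranked$image_id)
  }
  ids <- names(ranked)
  missing <- ids[!(ids %in% names(answered)) |
                 !lengths(answered[ids])]
  if (length(missing))
    stop("no answered SSWs for image(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  hits <- vapply(ids, function(id) {
    cand <- ranked[[id]]
    length(cand) >= rank &&
      canonicalSSW(cand[rank]) %in% canonicalSSW(answered[[id]])
  }, logical(1))
  mean(hits)
}

## Rank-1..ranks accuracy for a raw output matrix (rows named by image id).
.rankAccuracy <- function(outputs, lexicon, answered, ranks = 2L) {
  lex <- .asLexicon(lexicon)
  enc <- .encodeMatrix(lex$ssw)
  L <- .lossMatrix(outputs, enc)
  acc <- vapply(seq_len(ranks), function(r) {
    cand <- apply(L, 1, function(row) {
      lex$ssw[order(row, -lex$count, lex$ssw)[r]]
    })
    mean(vapply(rownames(outputs), function(id)
      cand[id] %in% answered[[id]], logical(1)))
  }, numeric(1))
  stats::setNames(acc, paste0("acc", seq_len(ranks)))
}

#' Rank lexicon candidates for a set of images
#'
#' Predicts each image's raw output, scores every lexicon word by the
#' composite cross-entropy loss, and reports the best candidates with
#' their correctness against the answered sets.
#'
#' @param model An \linkS4class{SSWModel} or \linkS4class{SSWFit}.
#' @param images Named list of image arrays to evaluate.
#' @param answered Named list of answered SSW sets per image (optional;
#'   without it \code{correct} is \code{NA}).
#' @param lexicon Candidate lexicon (data frame \code{ssw}, \code{count},
#'   named counts, or character vector); evaluation is restricted to it.
#' @param ranks Number of candidates to keep per image.
#' @return Data frame \code{image_id}, \code{rank}, \code{candidate},
#'   \code{loss}, \code{correct}.
#' @export
evaluateModel <- function(model, images, lexicon, answered = NULL,
                          ranks = 3L) {
  lex <- .asLexicon(lexicon)
  if (!nrow(lex)) stop("empty lexicon", call. = FALSE)
  outputs <- predictPhonemes(model, images)
  enc <- .encodeMatrix(lex$ssw)
  L <- .lossMatrix(outputs, enc)
  res <- do.call(rbind, lapply(rownames(L), function(id) {
    ord <- order(L[id, ], -lex$count, lex$ssw)[seq_len(min(ranks, nrow(lex)))]
    data.frame(image_id = id, rank = seq_along(ord),
               candidate = lex$ssw[ord], loss = unname(L[id, ord]),
               correct = if (is.null(answered)) NA else
                 lex$ssw[ord] %in% canonicalSSW(answered[[id]]),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Per-epoch accuracy-rate curve of a fit
#'
#' Returns the learning-curve columns tracked during training (see the
#' \code{trackAccuracy} argument of [trainModel()]): one row per epoch
#' with held-out rank-1 and rank-2 accuracy.
#'
#' @param fit An \linkS4class{SSWFit} trained with accuracy tracking.
#' @return Data frame \code{epoch}, \code{acc1}, \code{acc2}.
#' @export
accuracyCurves <- function(fit) {
  stopifnot(is(fit, "SSWFit"))
  cv <- fit@curve
  if (all(is.na(cv$acc1)))
    stop("fit was trained without accuracy tracking; pass trackAccuracy to trainModel()",
         call. = FALSE)
  cv[c("epoch", "acc1", "acc2")]
}

#' Label-permutation baseline accuracy
#'
#' Re-runs the identical pipeline after randomly reassigning whole
#' annotation sets across images (so every image keeps a plausible answer
#' set, but the image-annotation link is severed), then reports held-out
#' rank-1 and rank-2 accuracy. This is the no-signal reference an informed
#' model must beat.
#'
#' @param corpus A \linkS4class{TextureCorpus}.
#' @param config Training configuration.
#' @param testImages Held-out image ids (evaluated against the original,
#'   unpermuted answered sets).
#' @param lexicon Evaluation lexicon; defaults to the corpus lexicon.
#' @param seed Permutation seed.
#' @return Named numeric \code{c(acc1 =, acc2 =)}.
#' @export
permutationBaseline <- function(corpus, config = smallModelConfig(),
                                testImages, lexicon = NULL, seed = 1L) {
  ann <- corpus@annotations
  ids <- names(corpus@images)
  perm <- .withSeed(seed, sample(ids))
  names(perm) <- ids
  permAnn <- ann
  permAnn$image_id <- unname(perm[ann$image_id])
  if (is.null(lexicon)) lexicon <- buildLexicon(ann)
  answered <- answeredSets(ann)
  ts <- makePairs(corpus@images, permAnn)
  fit <- trainModel(ts, config, testImages = testImages)
  outs <- predictPhonemes(fit, corpus@images[testImages])
  .rankAccuracy(outs, lexicon, answered, ranks = 2L)
}

#' Write evaluation results / curves as CSV
#'
#' @param x Results data frame from [evaluateModel()] or a curve from
#'   [accuracyCurves()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeResultsCSV <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
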