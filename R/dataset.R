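## Corpus assembly: mark-based cropping, annotation/lexicon I/O, training
## pairs and fold bookkeeping. Pixel conventions: 0-based coordinates,
## origin top-left, x = column, y = row; crops are half-open intervals.

#' Crop image regions marked by several participants
#'
#' Participants mark the image point they focused on; marks are clustered
#' by single linkage with link distance \code{cropSize/2}, and every
#' cluster marked by at least \code{minMarks} distinct participants yields
#' one square crop centered on the cluster centroid, clamped to the image
#' bounds.
#'
#' @param image H x W x 3 array in [0,1].
#' @param marks Data frame with columns \code{participant_id}, \code{x},
#'   \code{y} (0-based pixel coordinates inside the image).
#' @param minMarks Minimum number of distinct participants per cluster.
#' @param cropSize Square crop edge in pixels.
#' @return List of \code{cropSize} x \code{cropSize} x 3 arrays.
#' @examples
#' img <- genTexture(textureParams(seed = 3), size = 200)
#' marks <- data.frame(participant_id = 1:3, x = c(40, 42, 44), y = 50)
#' length(cropMarkedRegions(img, marks, cropSize = 150))
#' @export
cropMarkedRegions <- function(image, marks, minMarks = 3L, cropSize = 150L) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < cropSize || W < cropSize)
    stop(sprintf("image (%d x %d) smaller than crop size %d", H, W,
                 cropSize), call. = FALSE)
  stopifnot(all(c("participant_id", "x", "y") %in% names(marks)))
  if (!nrow(marks)) return(list())
  if (any(marks$x < 0 | marks$x >= W | marks$y < 0 | marks$y >= H))
    stop("mark coordinates outside the image bounds", call. = FALSE)
  xy <- cbind(marks$x, marks$y)
  cl <- if (nrow(xy) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(xy), method = "single"),
                  h = cropSize / 2)
  crops <- list()
  for (k in sort(unique(cl))) {
    sel <- cl == k
    if (length(unique(marks$participant_id[sel])) < minMarks) next
    cx <- mean(marks$x[sel]); cy <- mean(marks$y[sel])
    ## 0-based top-left corner, clamped so the crop fits
    x0 <- min(max(round(cx - cropSize / 2), 0), W - cropSize)
    y0 <- min(max(round(cy - cropSize / 2), 0), H - cropSize)
    crops[[length(crops) + 1L]] <-
      image[y0 + seq_len(cropSize), x0 + seq_len(cropSize), , drop = FALSE]
  }
  crops
}

#' Build a frequency lexicon from annotations
#'
#' Tokens are canonicalized with [canonicalSSW()] (so spelling variants
#' collapse to one type) and counted; counts conserve the token total.
#'
#' @param annotations Data frame with a column \code{ssw}, one row per
#'   token (the long format produced by [readAnnotations()] and
#'   [genCorpus()]).
#' @param skipUnparseable Drop unparseable tokens with a warning instead
#'   of failing.
#' @return Data frame \code{ssw} (canonical), \code{count}, ordered by
#'   descending count then lexicographically.
#' @export
buildLexicon <- function(annotations, skipUnparseable = FALSE) {
  stopifnot("ssw" %in% names(annotations))
  tokens <- annotations$ssw
  if (!length(tokens))
    return(data.frame(ssw = character(), count = integer(),
                      stringsAsFactors = FALSE))
  canon <- character(length(tokens))
  for (i in seq_along(tokens)) {
    canon[i] <- tryCatch(canonicalSSW(tokens[i]), error = function(e) {
      if (skipUnparseable) {
        warning(sprintf("skipping row %d: %s", i, conditionMessage(e)),
                call. = FALSE)
        NA_character_
      } else stop(sprintf("row %d: %s", i, conditionMessage(e)),
                  call. = FALSE)
    })
  }
  canon <- canon[!is.na(canon)]
  tab <- table(canon)
  lex <- data.frame(ssw = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  lex <- lex[order(-lex$count, lex$ssw), ]
  rownames(lex) <- NULL
  lex
}

#' Pair every annotation token with its image
#'
#' One training pair per token (an image annotated with k tokens appears in
#' k pairs, duplicates kept as duplicates); each target is the 88-bit
#' encoding of the token's canonical form.
#'
#' @param images Named list of H x W x 3 arrays; names are image ids.
#' @param annotations Long data frame \code{image_id},
#'   \code{participant_id}, \code{ssw}.
#' @return An \linkS4class{SSWTrainingSet} whose pair count equals the
#'   token count.
#' @export
makePairs <- function(images, annotations) {
  stopifnot(all(c("image_id", "ssw") %in% names(annotations)))
  missing <- setdiff(unique(annotations$image_id), names(images))
  if (length(missing))
    stop("annotations reference missing image(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  canon <- canonicalSSW(annotations$ssw)
  types <- unique(canon)
  enc <- .encodeMatrix(types)
  samples <- data.frame(image_id = as.character(annotations$image_id),
                        ssw = canon, stringsAsFactors = FALSE)
  new("SSWTrainingSet", images = images, samples = samples,
      targets = enc[match(canon, types), , drop = FALSE])
}

#' Nominal train/test sizes of a k-fold split
#'
#' The held-out fold holds \code{round(n / folds)} images and training the
#' remainder: 1,946 images in 10 folds give the nominal 195 test / 1,751
#' training images.
#'
#' @param n Number of images.
#' @param folds Number of folds.
#' @return Named integer vector \code{c(train =, test =)}.
#' @export
foldSizes <- function(n, folds) {
  test <- as.integer(round(n / folds))
  c(train = as.integer(n) - test, test = test)
}

#' Assign image ids to disjoint folds
#'
#' Shuffles ids reproducibly (when \code{seed} is given) and deals them
#' round-robin, so fold sizes differ by at most one and every id belongs
#' to exactly one fold. Assignment is by image id: pairs sharing an image
#' can never span train and test.
#'
#' @param imageIds Character vector of unique image ids.
#' @param folds Number of folds.
#' @param seed Optional shuffle seed; without it, ids are dealt in order.
#' @return Integer fold index (1..folds) per id, named by id.
#' @export
assignFolds <- function(imageIds, folds, seed = NULL) {
  stopifnot(!anyDuplicated(imageIds))
  if (length(imageIds) < folds)
    stop("fewer images than folds", call. = FALSE)
  ord <- if (is.null(seed)) seq_along(imageIds)
         else .withSeed(seed, sample.int(length(imageIds)))
  fold <- integer(length(imageIds))
  fold[ord] <- rep_len(seq_len(folds), length(imageIds))
  names(fold) <- imageIds
  fold
}

## ---- Plain-text I/O -------------------------------------------------------

#' Read and write corpus tables
#'
#' Annotations TSV: \code{image_id<TAB>participant_id<TAB>ssw1;ssw2;...},
#' expanded to/collapsed from one row per token. Marks TSV:
#' \code{image_id<TAB>participant_id<TAB>x<TAB>y}. Lexicon TSV:
#' \code{ssw<TAB>count}.
#'
#' @param path File path.
#' @return \code{readAnnotations()}: long data frame \code{image_id},
#'   \code{participant_id}, \code{ssw}; \code{readMarks()} and
#'   \code{readLexicon()}: the corresponding data frame.
#' @export
readAnnotations <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  stopifnot(all(c("image_id", "participant_id", "ssw") %in% names(raw)))
  toks <- strsplit(raw$ssw, ";", fixed = TRUE)
  n <- lengths(toks)
  if (any(n < 1L | n > 6L))
    stop(sprintf("%s: row %d has %d tokens (1-6 allowed)", path,
                 which(n < 1L | n > 6L)[1], n[n < 1L | n > 6L][1]),
         call. = FALSE)
  data.frame(image_id = rep(raw$image_id, n),
             participant_id = rep(raw$participant_id, n),
             ssw = unlist(toks), stringsAsFactors = FALSE)
}

#' @rdname readAnnotations
#' @param annotations Long annotation data frame.
#' @export
writeAnnotations <- function(annotations, path) {
  key <- paste(annotations$image_id, annotations$participant_id, sep = "\r")
  agg <- vapply(split(annotations$ssw, key), paste, character(1),
                collapse = ";")
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(image_id = vapply(parts, `[`, "", 1),
                    participant_id = vapply(parts, `[`, "", 2),
                    ssw = unname(agg), stringsAsFactors = FALSE)
  out <- out[order(out$image_id, out$participant_id), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readAnnotations
#' @export
readMarks <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("image_id", "participant_id", "x", "y") %in% names(m)))
  m
}

#' @rdname readAnnotations
#' @export
readLexicon <- function(path) {
  lex <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  stopifnot(all(c("ssw", "count") %in% names(lex)))
  lex
}

#' @rdname readAnnotations
#' @param lexicon Lexicon data frame \code{ssw}, \code{count}.
#' @export
writeLexicon <- function(lexicon, path) {
  utils::write.table(lexicon[c("ssw", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
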