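# Semantic space: per-scene vectors from annotations and an embedding table,
# category vectors, and the PCA basis used by the projected accuracy measure.

#' Construct an embedding table
#'
#' An embedding table maps tokens to D-dimensional word vectors and is the
#' semantic currency of the pipeline.  Stored as a numeric matrix with one
#' row per token (rownames are the tokens).
#'
#' @param vectors Numeric matrix, tokens x D, with unique rownames.
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors)))
    stop_invalid("embedding rows must carry unique token names")
  if (ncol(vectors) < 1) stop_invalid("embedding dimension must be >= 1")
  structure(vectors, class = c("embedding_table", "matrix", "array"))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("Embedding table: %d tokens, %d dimensions\n", nrow(x), ncol(x)))
  invisible(x)
}

embedding_dim <- function(embedding) ncol(embedding)

lookup_tokens <- function(embedding, tokens) {
  tokens[tokens %in% rownames(embedding)]
}

#' Tokenize annotation text
#'
#' Default tokenizer: lowercase, split on whitespace and punctuation.  The
#' tokenizer is pluggable so that language-specific morphological analyzers
#' can be substituted; tokens absent from the embedding vocabulary are
#' dropped downstream, not here.
#'
#' @param text Character scalar (may be empty).
#' @param tokenizer Optional function `character(1) -> character()` replacing
#'   the default.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, tokenizer = NULL) {
  if (!is.null(tokenizer)) return(tokenizer(text))
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[[:space:][:punct:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Build one scene's semantic vector from its annotations
#'
#' Word vectors are averaged first within each annotation, then across the
#' annotators, exploiting the linearity of the embedding space.  Tokens not
#' present in the embedding vocabulary are discarded; annotations left empty
#' after that filtering are dropped from the outer average.
#'
#' @param annotations List of character vectors, one element per annotator
#'   (each a bag of tokens), or a list of raw strings to be passed through
#'   [tokenize()].
#' @param embedding An [embedding_table()].
#' @param scene_id Optional identifier used in error messages.
#' @param tokenizer Optional tokenizer forwarded to [tokenize()].
#' @return Numeric D-vector.
#' @export
build_scene_vector <- function(annotations, embedding, scene_id = NULL,
                               tokenizer = NULL) {
  if (length(annotations) < 1) stop_invalid("at least one annotation required")
  per_annotator <- lapply(annotations, function(a) {
    # length-1 elements are raw annotation strings; longer ones are token bags
    toks <- if (length(a) <= 1) tokenize(a, tokenizer) else as.character(a)
    toks <- lookup_tokens(embedding, toks)
    if (length(toks) == 0) return(NULL)
    colMeans(embedding[toks, , drop = FALSE])
  })
  per_annotator <- per_annotator[!vapply(per_annotator, is.null, logical(1))]
  if (length(per_annotator) == 0)
    stop_invalid("no usable tokens for scene %s: all annotations empty after vocabulary filtering",
                 scene_id %||% "<unnamed>")
  colMeans(do.call(rbind, per_annotator))
}

#' Category vectors for word, landscape and human face
#'
#' The "word" and "landscape" category vectors are the embedding vectors of
#' those tokens; the "face" vector is the average of the vectors for
#' "human" and "face".
#'
#' @param embedding An [embedding_table()] containing tokens `word`,
#'   `landscape`, `human` and `face`.
#' @return List with elements `word`, `landscape`, `face` (D-vectors).
#' @export
category_vectors <- function(embedding) {
  need <- c("word", "landscape", "human", "face")
  missing <- setdiff(need, rownames(embedding))
  if (length(missing) > 0)
    stop_invalid("missing vocabulary token(s): %s", paste(missing, collapse = ", "))
  list(word = embedding["word", ],
       landscape = embedding["landscape", ],
       face = (embedding["human", ] + embedding["face", ]) / 2)
}

category_matrix <- function(cats) {
  cbind(word = cats$word, landscape = cats$landscape, face = cats$face)
}

#' PCA basis of a semantic matrix
#'
#' Centered-data PCA of the scene-by-dimension matrix of true semantic
#' vectors.  Components are ordered by nonincreasing explained variance and
#' each direction vector's sign is fixed so that its largest-magnitude
#' loading is positive, making projected scores reproducible across runs.
#'
#' @param V Numeric matrix, scenes x D.
#' @return Object of class `semantic_pca` with fields `mean` (D-vector),
#'   `directions` (D x K orthonormal), `explained_variance` (length K),
#'   `scores` (scenes x K).
#' @export
fit_pca <- function(V) {
  V <- as.matrix(V)
  if (nrow(V) < 2) stop_invalid("PCA requires at least 2 scenes")
  if (!all(is.finite(V))) stop_invalid("PCA input must be finite")
  if (all(apply(V, 2, stats::sd) == 0)) stop_invalid("degenerate input: constant matrix")
  p <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each direction positive
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    v <- p$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  directions <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  structure(list(mean = p$center,
                 directions = directions,
                 explained_variance = p$sdev^2,
                 scores = scores),
            class = "semantic_pca")
}

#' @export
print.semantic_pca <- function(x, ...) {
  cat(sprintf("Semantic-space PCA: %d directions; top variance %.4g\n",
              ncol(x$directions), x$explained_variance[1]))
  invisible(x)
}

#' Project semantic vectors onto a PCA direction
#'
#' @param pca A [fit_pca()] result.
#' @param V Matrix of vectors (rows) in the original space.
#' @param k Component index.
#' @return Numeric vector of projected scores.
#' @export
pca_project <- function(pca, V, k) {
  if (k < 1 || k > ncol(pca$directions)) stop_invalid("component k out of range")
  drop(sweep(as.matrix(V), 2, pca$mean) %*% pca$directions[, k])
}

#' Select the scenes most representative of a category
#'
#' Ranks scenes by the Pearson correlation of their true semantic vector with
#' the category vector and returns the indices of the top `n`.  Ties are
#' broken in favour of the lower scene index; zero-variance scene vectors
#' correlate 0 by the package-wide rule.
#'
#' @param V_true Scenes x D matrix.
#' @param category_vector D-vector.
#' @param n Number of scenes to select.
#' @return Integer vector of scene indices, ordered by decreasing correlation.
#' @export
select_category_scenes <- function(V_true, category_vector, n) {
  V_true <- as.matrix(V_true)
  if (n > nrow(V_true)) stop_invalid("n exceeds the number of scenes")
  r <- drop(cor_cols_safe(t(V_true), matrix(category_vector, ncol = 1)))
  ord <- order(-r, seq_along(r))
  ord[seq_len(n)]
}

#' Annotator consistency of a scene
#'
#' Mean pairwise Pearson correlation between the per-annotator vectors of one
#' scene (each annotator's vector is the mean embedding of their tokens).
#'
#' @param annotations List of token bags, one per annotator.
#' @param embedding An [embedding_table()].
#' @return Mean pairwise correlation (1 when all annotators agree exactly).
#' @export
annotator_consistency <- function(annotations, embedding) {
  vecs <- lapply(annotations, function(a) {
    toks <- lookup_tokens(embedding, as.character(a))
    if (length(toks) == 0) return(NULL)
    colMeans(embedding[toks, , drop = FALSE])
  })
  vecs <- vecs[!vapply(vecs, is.null, logical(1))]
  if (length(vecs) < 2) stop_invalid("need >= 2 annotators with usable tokens")
  M <- do.call(cbind, vecs)
  pairs <- utils::combn(ncol(M), 2)
  mean(apply(pairs, 2, function(p) cor_safe(M[, p[1]], M[, p[2]], warn = FALSE)))
}
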