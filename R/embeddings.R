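# Token-embedding layer: a frozen context-independent lookup table,
# optionally concatenated with precomputed per-sentence contextualized
# vectors, followed by layer normalization.  Biomedical case matters, so
# tokens are looked up case-sensitively; out-of-vocabulary tokens map to a
# reserved "<UNK>" row.

UNK_TOKEN <- "<UNK>"

#' Embedding table
#'
#' @param vectors numeric matrix, one row per vocabulary token.
#' @param vocab character vector of tokens, one per row.  A `"<UNK>"` row is
#'   appended (as the zero vector) when absent.
#' @return An `embedding_table`: list with `vectors` (|V| x d_w, rownames =
#'   vocab) and `d_w`.
#' @export
embedding_table <- function(vectors, vocab = rownames(vectors)) {
  vectors <- as.matrix(vectors)
  if (is.null(vocab) || length(vocab) != nrow(vectors))
    stop("vocab must name every row of the vector matrix")
  if (anyDuplicated(vocab)) stop("duplicate tokens in vocabulary")
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  if (!(UNK_TOKEN %in% vocab)) {
    vectors <- rbind(vectors, 0)
    vocab <- c(vocab, UNK_TOKEN)
  }
  rownames(vectors) <- vocab
  structure(list(vectors = vectors, d_w = ncol(vectors)),
            class = "embedding_table")
}

#' Read a word2vec text-format embedding file
#'
#' Accepts both dialects: with an optional leading `"<count> <dim>"` header
#' line, then one `"token v1 ... vd"` line per type.
#'
#' @param path file to read.
#' @return An [embedding_table()] (a `"<UNK>"` zero row is added if the file
#'   has none).
#' @export
load_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop("malformed embedding line: ", lines[[1]])
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad) > 0L)
    stop("inconsistent vector dimension at line ", bad[[1]],
         " (expected ", d, ")")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vectors <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                    nrow = length(parts), ncol = d, byrow = TRUE)
  if (anyNA(vectors)) stop("non-numeric vector entries in ", path)
  if (has_header && as.integer(first[[1]]) != length(vocab))
    warning("header count ", first[[1]], " != ", length(vocab), " vectors")
  embedding_table(vectors, vocab)
}

#' Contextual-vector store
#'
#' Holds precomputed per-sentence contextualized token vectors keyed by a
#' sentence identifier (e.g. `"train/17"`).
#'
#' @param matrices named list of N_s x d_ctx matrices.
#' @return A `contextual_store`.
#' @export
contextual_store <- function(matrices) {
  if (length(matrices) > 0L && is.null(names(matrices)))
    stop("contextual matrices must be named by sentence key")
  dims <- vapply(matrices, ncol, integer(1))
  if (length(unique(dims)) > 1L)
    stop("all contextual matrices must share one dimension")
  structure(list(matrices = matrices,
                 d_ctx = if (length(dims) > 0L) dims[[1]] else 0L),
            class = "contextual_store")
}

#' Embed the tokens of one sentence
#'
#' Row `i` of the result is the lookup vector of token `i` (the `"<UNK>"` row
#' for out-of-vocabulary tokens) concatenated with its contextualized vector
#' when a store is supplied.  No normalization is applied here; see
#' [layer_normalize()].
#'
#' @param sentence a [labeled_sentence()] (or any list with `$tokens`).
#' @param table an [embedding_table()].
#' @param store optional [contextual_store()].
#' @param key sentence identifier inside `store`.
#' @return N x d_e numeric matrix, `d_e = d_w + d_ctx`.
#' @export
embed_tokens <- function(sentence, table, store = NULL, key = NULL) {
  tokens <- sentence$tokens
  idx <- match(tokens, rownames(table$vectors))
  idx[is.na(idx)] <- match(UNK_TOKEN, rownames(table$vectors))
  mat <- table$vectors[idx, , drop = FALSE]
  if (!is.null(store)) {
    if (is.null(key) || !(key %in% names(store$matrices)))
      stop("sentence key ", if (is.null(key)) "<missing>" else key,
           " not found in contextual store")
    ctx <- store$matrices[[key]]
    if (nrow(ctx) != length(tokens))
      stop("contextual matrix for ", key, " has ", nrow(ctx),
           " rows but the sentence has ", length(tokens), " tokens")
    mat <- cbind(mat, ctx)
  }
  dimnames(mat) <- NULL
  mat
}

#' Fraction of tokens mapped to the unknown-word vector
#'
#' @param corpus a [ner_corpus()].
#' @param table an [embedding_table()].
#' @return scalar in `[0, 1]`.
#' @export
oov_rate <- function(corpus, table) {
  tokens <- unlist(lapply(corpus, `[[`, "tokens"))
  mean(!(tokens %in% setdiff(rownames(table$vectors), UNK_TOKEN)))
}

#' Layer normalization
#'
#' Normalizes each row to zero mean and unit variance over its entries, then
#' applies an element-wise gain and bias.
#'
#' @param matrix numeric matrix (rows are normalized independently).
#' @param gain,bias numeric vectors of length `ncol(matrix)` (defaults: unit
#'   gain, zero bias).
#' @param epsilon variance floor guarding constant rows.
#' @return matrix of the same shape.
#' @export
layer_normalize <- function(matrix, gain = rep(1, ncol(matrix)),
                            bias = rep(0, ncol(matrix)), epsilon = 1e-5) {
  matrix <- as.matrix(matrix)
  mu <- rowMeans(matrix)
  centered <- matrix - mu
  v <- rowMeans(centered^2)
  normalized <- centered / sqrt(v + epsilon)
  sweep(sweep(normalized, 2L, gain, `*`), 2L, bias, `+`)
}
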