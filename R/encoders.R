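# Sequence and condition encoders: anomaly substitution, position one-hot,
# anomaly position/type flags, temperature one-hot, incubation pair, cargo
# multi-hot.

#' Load the anomaly substitution map
#'
#' Maps anomalous sequence tokens (lowercase d-residues, ambiguity codes,
#' bracketed modification tokens) to their closest standard amino acid and a
#' substitution-type label. The packaged default is a synthetic 56-type
#' vocabulary (the field's curated tables are not redistributable); 46 types
#' are flagged `observed` and featurized, the remainder are kept in the
#' vocabulary only.
#'
#' @param path CSV with columns `token,replacement,type,observed`
#'   (default: packaged map).
#' @return data.frame with those columns.
#' @export
load_anomaly_map <- function(path = extdata_path("config", "anomaly_map.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (any(!df$replacement %in% AA20))
    abort("every anomaly replacement must be a standard amino acid", "config_error")
  if (anyDuplicated(df$type))
    abort("substitution-type labels must be unique", "config_error")
  df$observed <- as.logical(df$observed)
  df
}

#' Load the cargo vocabulary
#'
#' @param path CSV with columns `label,synonyms` (default: packaged 63-label
#'   synthetic vocabulary).
#' @return data.frame with `label` and a list-column `synonyms`.
#' @export
load_cargo_vocab <- function(path = extdata_path("config", "cargo_vocab.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$synonyms <- lapply(df$synonyms, function(s)
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]])
  df
}

# split a raw sequence into tokens: bracketed groups count as one token
tokenize_sequence <- function(raw_seq) {
  if (!nzchar(raw_seq)) return(character(0))
  m <- gregexpr("\\[[^][]*\\]|.", raw_seq)[[1]]
  regmatches(raw_seq, list(m))[[1]]
}

#' Substitute anomalous tokens with their closest standard residues
#'
#' @param raw_seq sequence possibly containing anomalous tokens (lowercase
#'   letters, ambiguity codes, `[...]` modification tokens).
#' @param map substitution map from [load_anomaly_map()].
#' @return list with `sequence` (clean, standard residues only) and
#'   `annotation`: data.frame of 1-based `position` (in the pre-substitution
#'   token sequence) and substitution `type`.
#' @export
substitute_anomalies <- function(raw_seq, map = load_anomaly_map()) {
  toks <- tokenize_sequence(raw_seq)
  std <- toks %in% AA20
  idx <- match(toks, map$token)
  unknown <- which(!std & is.na(idx))
  if (length(unknown))
    abort(sprintf("token '%s' at position %d has no substitution rule",
                  toks[unknown[1]], unknown[1]), "validation_error")
  anom <- which(!std)
  clean <- toks
  clean[anom] <- map$replacement[idx[anom]]
  list(sequence = paste(clean, collapse = ""),
       annotation = data.frame(position = anom,
                               type = map$type[idx[anom]],
                               stringsAsFactors = FALSE))
}

#' Position one-hot encoding of a clean sequence
#'
#' Column `(i, a)` is 1 iff residue `i` is amino acid `a`; positions beyond
#' the sequence end are zero padding. Layout is position-major with residues
#' in alphabetical order.
#'
#' @param clean_seq standard-residue sequence of length `<= max_len`.
#' @param max_len padding length (default 100, the dataset maximum; longer
#'   sequences are rejected rather than truncated).
#' @return numeric vector of `20 * max_len` indicators.
#' @export
encode_positions <- function(clean_seq, max_len = 100L) {
  res <- check_standard_seq(clean_seq, allow_empty = TRUE)
  if (length(res) > max_len)
    abort(sprintf("sequence length %d exceeds maximum %d", length(res), max_len),
          "validation_error")
  v <- numeric(20L * max_len)
  if (length(res))
    v[(seq_along(res) - 1L) * 20L + match(res, AA20)] <- 1
  v
}

#' Anomaly position/type indicator block
#'
#' 24 position indicators (substitutions at positions 1..24; later positions
#' are ignored with a warning) followed by one indicator per observed
#' substitution type.
#'
#' @param annotation annotation data.frame from [substitute_anomalies()].
#' @param map substitution map defining the type vocabulary.
#' @param max_pos number of featurized positions.
#' @return numeric indicator vector (70 columns with the packaged map).
#' @export
encode_anomalies <- function(annotation, map = load_anomaly_map(), max_pos = 24L) {
  obs_types <- map$type[map$observed]
  pos_block <- numeric(max_pos)
  type_block <- numeric(length(obs_types))
  if (nrow(annotation)) {
    bad <- !annotation$type %in% map$type
    if (any(bad))
      abort(sprintf("unknown substitution type '%s'", annotation$type[bad][1]),
            "validation_error")
    over <- annotation$position > max_pos
    if (any(over))
      warning(sprintf("%d substitution(s) beyond position %d not featurized",
                      sum(over), max_pos))
    pos_block[unique(annotation$position[!over])] <- 1
    type_block[match(intersect(annotation$type, obs_types), obs_types)] <- 1
  }
  c(pos_block, type_block)
}

#' Temperature one-hot encoding
#'
#' @param label temperature category label.
#' @param levels closed category set; exactly five categories, membership
#'   configurable.
#' @return one-hot vector over `levels`.
#' @export
encode_temperature <- function(label, levels = c("4", "25", "37", "other", "unknown")) {
  i <- match(as.character(label), levels)
  if (is.na(i))
    abort(sprintf("temperature label '%s' not in category set {%s}; use 'other'",
                  label, paste(levels, collapse = ", ")), "validation_error")
  v <- numeric(length(levels))
  v[i] <- 1
  v
}

#' Incubation-time pair encoding
#'
#' @param available logical availability flag.
#' @param minutes incubation duration in minutes (ignored when unavailable).
#' @return numeric pair `(indicator, minutes)`; `(0, 0)` when unavailable.
#' @export
encode_incubation <- function(available, minutes = NA_real_) {
  if (!isTRUE(available)) return(c(0, 0))
  if (is.na(minutes) || minutes < 0)
    abort("incubation minutes must be non-negative when available", "domain_error")
  c(1, minutes)
}

#' Cargo multi-hot encoding
#'
#' @param cargoes character vector of 0, 1 or 2 cargo labels.
#' @param vocab cargo vocabulary from [load_cargo_vocab()].
#' @return multi-hot vector over the vocabulary (duplicates collapse).
#' @export
encode_cargo <- function(cargoes, vocab = load_cargo_vocab()) {
  if (length(cargoes) > 2) abort("at most two cargoes per record", "validation_error")
  v <- numeric(nrow(vocab))
  if (!length(cargoes)) return(v)
  i <- match(cargoes, vocab$label)
  if (anyNA(i)) {
    missing_label <- cargoes[is.na(i)][1]
    d <- utils::adist(missing_label, vocab$label, ignore.case = TRUE)
    near <- vocab$label[order(d)][1:3]
    abort(sprintf("unknown cargo label '%s'; nearest vocabulary entries: %s",
                  missing_label, paste(near, collapse = ", ")), "validation_error")
  }
  v[unique(i)] <- 1
  v
}

#' Map a free-text cargo spelling onto the vocabulary
#'
#' @param label raw cargo spelling.
#' @param vocab cargo vocabulary with synonyms.
#' @return canonical label, or `NA` if no match.
#' @export
canonical_cargo <- function(label, vocab = load_cargo_vocab()) {
  l <- tolower(trimws(label))
  hit <- which(tolower(vocab$label) == l |
                 vapply(vocab$synonyms, function(s) l %in% tolower(s), logical(1)))
  if (length(hit)) vocab$label[hit[1]] else NA_character_
}
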