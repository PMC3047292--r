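#' Pseudonymise a practice-internal patient identifier
#'
#' Replaces the internal patient ID by a study ID that cannot be traced back
#' to it without the practice-local key: an HMAC-SHA256 keyed digest of the
#' internal ID under a per-practice secret, truncated to 32 hex characters
#' and prefixed with `"S"`. The mapping is deterministic for a fixed
#' `(internal_id, practice_secret)` pair and injective over any realistic
#' practice panel; re-identification requires the key map held only at the
#' practice.
#'
#' @param internal_id Character vector of practice-local identifiers
#'   (non-empty strings).
#' @param practice_secret A single non-empty string: the practice-local key.
#' @return Character vector of study IDs, same length as `internal_id`.
#' @examples
#' pseudonymize(c("PAT001", "PAT002"), practice_secret = "s3cret")
#' @export
pseudonymize <- function(internal_id, practice_secret) {
  internal_id <- as.character(internal_id)
  if (length(practice_secret) != 1L || is.na(practice_secret) || !nzchar(practice_secret)) {
    rlang::abort("`practice_secret` must be a single non-empty string", class = "cta_invalid_input")
  }
  if (length(internal_id) == 0L || any(is.na(internal_id)) || any(!nzchar(internal_id))) {
    rlang::abort("`internal_id` must be non-empty", class = "cta_invalid_input")
  }
  vapply(
    internal_id,
    function(id) paste0("S", substr(digest::hmac(practice_secret, id, algo = "sha256"), 1L, 32L)),
    character(1),
    USE.NAMES = FALSE
  )
}
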