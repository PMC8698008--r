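`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x, min = 0L) {
    length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min &&
        x == as.integer(x)
}

.is_prob <- function(x) {
    length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

.is_flag <- function(x) length(x) == 1L && is.logical(x) && !is.na(x)

#' Log-sum-exp of a numeric vector
#' @noRd
.logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' MD5 of an R object via its serialized JSON form
#' @noRd
.object_md5 <- function(x) {
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf))
    jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    unname(tools::md5sum(tf))
}
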