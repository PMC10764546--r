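#' Derive independent child seeds from a master seed
#'
#' Deterministically expands one master seed into \code{n} child seeds (all
#' below 2^31) so pipeline stages and per-region fits can be rerun
#' independently yet reproducibly. The master RNG state is restored
#' afterwards.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}.
#' @export
deriveSeeds <- function(master, n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(master))
    sample.int(.Machine$integer.max - 1L, n)
}

#' Hash a configuration object
#'
#' MD5 of the canonical serialization of a configuration (version-2
#' serialization, so the hash is stable across R sessions). Logged with
#' every pipeline run: the hash changes iff any setting changes.
#'
#' @param config any R object.
#' @return 32-character hex string.
#' @export
configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    con <- file(f, "wb")
    serialize(config, con, version = 2)
    close(con)
    unname(tools::md5sum(f))
}
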