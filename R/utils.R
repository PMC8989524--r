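## Small shared helpers: hashed, header-bearing TSV writers and config IO.

## FNV-1a hash of a character vector, for config fingerprints in output
## headers.
fnvHash <- function(x) {
    bytes <- utf8ToInt(paste(x, collapse = "\n"))
    h <- 2166136261
    for (b in bytes) {
        ## xor on the low 16 bits keeps everything inside integer range
        lo <- h %% 65536
        h <- h - lo + bitwXor(lo, b)
        h <- (h * 16777619) %% 4294967296
    }
    ## h < 2^32 may exceed integer range; format the two 16-bit halves
    sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

configHash <- function(config) fnvHash(deparse(config, control = "all"))

## Write a TSV with a header comment recording the producing stage and the
## run's config hash.
writeStageTable <- function(df, path, stage, hash) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# stage=%s config_hash=%s", stage, hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

readStageTable <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE)
}
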