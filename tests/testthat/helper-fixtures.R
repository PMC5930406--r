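# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests themselves write to
# tempfiles.

# A hand-built toy design: nProteins proteins in duplicate laid out row-major
# over the given grid, plus optional control spots appended at the grid tail.
toy_design <- function(nProteins = 4, nBlocks = 2, blockRows = 2,
                       blockCols = 2, controls = 0) {
    capacity <- nBlocks * blockRows * blockCols
    stopifnot(capacity >= 2 * nProteins + controls)
    grid <- expand.grid(col = seq_len(blockCols), row = seq_len(blockRows),
                        block = seq_len(nBlocks))
    n <- 2 * nProteins
    sub <- data.frame(block = grid$block[1:n], row = grid$row[1:n],
                      col = grid$col[1:n],
                      protein_id = rep(sprintf("P%02d", 1:nProteins), each = 2),
                      gene_symbol = rep(sprintf("G%02d", 1:nProteins), each = 2),
                      role = "substrate",
                      dup_group = rep(sprintf("D%02d", 1:nProteins), each = 2),
                      stringsAsFactors = FALSE)
    spots <- sub
    if (controls > 0) {
        idx <- (n + 1):(n + controls)
        ctl <- data.frame(block = grid$block[idx], row = grid$row[idx],
                          col = grid$col[idx],
                          protein_id = "CTRL", gene_symbol = "CTRL",
                          role = rep(c("negative_control", "positive_control",
                                       "landmark"), length.out = controls),
                          dup_group = NA_character_, stringsAsFactors = FALSE)
        spots <- rbind(spots, ctl)
    }
    new("ArrayDesign", nBlocks = as.integer(nBlocks),
        blockRows = as.integer(blockRows), blockCols = as.integer(blockCols),
        spots = spots)
}

# Scan with given per-spot ratios on a design: background fixed at 100,
# foreground = 100 * ratio (ratios aligned with designSpots order).
scan_from_ratios <- function(design, ratios,
                             condition = conditionLabel("x1", "PIAS1", "SUMO1"),
                             replicate = 1L, flags = NULL) {
    sp <- designSpots(design)
    stopifnot(length(ratios) == nrow(sp))
    m <- data.frame(block = sp$block, row = sp$row, col = sp$col,
                    foreground = 100 * ratios, background = 100,
                    flag = flags %||% rep("ok", nrow(sp)),
                    stringsAsFactors = FALSE)
    new("ArrayScan", condition = condition, replicate = as.integer(replicate),
        measurements = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal GenePix-style GPR text for a design subset.
gpr_text <- function(rows) {
    c("ATF\t1.0", "4\t8", '"Type=GenePix Results 3"',
      '"Scanner=toy"', '"Wavelengths=532"', '"PixelSize=10"',
      paste(c('"Block"', '"Row"', '"Column"', '"ID"', '"F532 Median"',
              '"B532 Median"', '"F532 % Sat."', '"Flags"'), collapse = "\t"),
      rows)
}

# Build a HitTable directly from a substrate vector.
hit_table <- function(condition, subs, e3dep = FALSE) {
    n <- length(subs)
    new("HitTable", condition = condition,
        hits = data.frame(substrate = sort(subs),
                          replicate_support = rep(3L, n),
                          mean_ratio = rep(10, n),
                          passed_negative_filter = rep(TRUE, n),
                          e3_dependent = rep(e3dep, n),
                          filters_passed = rep("ksd,consensus", n),
                          stringsAsFactors = FALSE))
}

random_aa <- function(n, len, seed) {
    set.seed(seed)
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    vapply(seq_len(n), function(i)
        paste(sample(alphabet, len, replace = TRUE), collapse = ""),
        character(1))
}
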