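# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# straight chain along x with canonical 3.8 A spacing
collinear_chain <- function(n, id = "line") {
  chain_structure(id, rep("A", n), cbind(3.8 * (seq_len(n) - 1), 0, 0))
}

# small trained pipeline: tables trained on an 8-family simulated set
test_tables <- function() {
  fixture("tables", function() {
    set <- make_benchmark_set(8, 3, sim_params(seed = 101, n_residues = 60))
    train_tables(set$chains, family_alignments(set), seed = 5)
  })
}

test_train_set <- function() {
  fixture("train_set", function()
    make_benchmark_set(8, 3, sim_params(seed = 101, n_residues = 60)))
}

# separate labeled benchmark set, never used for training
test_bench_set <- function() {
  fixture("bench_set", function()
    make_benchmark_set(10, 4, sim_params(seed = 202, n_residues = 60)))
}

# calibrated tables: E-value null fitted on the benchmark set's chains
test_tables_calibrated <- function() {
  fixture("tables_cal", function()
    calibrate_evalues(test_tables(), test_bench_set()$chains))
}

# a tiny single-feature table bundle over a 2-letter alphabet, for DP tests
toy_matrices <- function(m11 = 1.5, m22 = 0.9, m12 = -1.1, weight = 1) {
  M <- matrix(c(m11, m12, m12, m22), 2, 2)
  structure(list(feature_order = "f1",
                 matrices = list(f1 = structure(
                   list(feature_name = "f1", size = 2L, matrix = M,
                        weight = weight),
                   class = "score_matrix")),
                 pseudocount = 0),
            class = "score_matrix_set")
}

toy_dfv <- function(letters) {
  matrix(as.integer(letters), ncol = 1L, dimnames = list(NULL, "f1"))
}

new_alignment_result_for_test <- function(q_cols, t_cols, score) {
  strataln:::new_alignment_result(q_cols, t_cols, score)
}

# minimal PDB text for IO tests
write_fixture_pdb <- function(path, lines) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, resno, x, y, z, chain = "A", resid = "ALA",
                          alt = " ", name = "CA") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, paste0(" ", name), alt, resid, chain, resno, x, y, z)
}
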