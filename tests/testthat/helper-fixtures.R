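# Shared fixtures, built in code.

# the four external-validation classifier rows (printed percentages /
# ratios at 2 d.p.) over a 55-positive / 54-negative validation set
table3_rows <- function() data.frame(
    model = c("RFR_QNPR", "XGBOOST_QNPR", "CNF", "Consensus"),
    q = c(87.16, 83.49, 83.49, 86.24),
    se = c(87.27, 85.45, 80.00, 85.45),
    sp = c(87.04, 81.48, 87.04, 87.04),
    ef = c(1.76, 1.71, 1.64, 1.72),
    mcc = c(0.74, 0.67, 0.67, 0.72),
    stringsAsFactors = FALSE)

# reported carrier counts of the 16 bundled alert bits (toxic-only)
alert_counts <- function() data.frame(
    bit_id = c("KR413", "KR848", "KR1798", "KR2444", "KR3206", "KR3280",
        "KR3540", "KR3548", "KR3586", "KR4029", "KR4064", "KR4065",
        "KR4081", "KR4252", "KR4556", "KR4651"),
    n_pos = c(9, 7, 8, 6, 7, 8, 7, 8, 12, 6, 8, 8, 6, 11, 8, 8),
    n_neg = 0L, stringsAsFactors = FALSE)

# small molecules (<= 15 heavy atoms) exercising matches and non-matches
# across the bundled patterns
oracle_fixture_smiles <- function() c(
    propylbenzene   = "CCCc1ccccc1",
    fluorotoluene_p = "Cc1ccc(F)cc1",
    fluorotoluene_m = "Cc1cccc(F)c1",
    difluorobenzene = "Fc1cccc(F)c1",
    fluoroaniline   = "Nc1ccc(F)cc1",
    fluorobenzaldehyde = "Fc1cccc(C=O)c1",
    benzonitrile    = "N#Cc1ccccc1",
    benzimidazole   = "c1ccc2[nH]cnc2c1",
    mt_benzimidazole = "CSc1nc2ccccc2[nH]1",
    aminoacetophenone = "CC(=O)c1ccc(N)cc1",
    methylbiphenyl  = "Cc1ccc(cc1)c2ccccc2",
    bisformamide    = "O=CNCCCCNC=O",
    proline         = "OC(=O)C1CCCN1",
    dipeptide_amide = "CNC(=O)C(C)NC(=O)C",
    dimethylpiperazine = "CN1CCN(C)CC1",
    ethanol         = "CCO",
    benzene         = "c1ccccc1",
    ibuprofen_core  = "CC(C)Cc1ccc(C)cc1",
    cyclohexanol    = "OC1CCCCC1",
    ethyl_fluorobenzene = "CCc1ccc(F)cc1")

# write a compound CSV and return its path
write_compound_csv <- function(df, path = tempfile(fileext = ".csv")) {
    write.csv(df, path, row.names = FALSE)
    path
}

small_compound_df <- function() data.frame(
    compound_id = c("c1", "c2", "c3"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
    label = c(1, 0, 1), stringsAsFactors = FALSE)
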