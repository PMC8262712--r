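{
  "format_version": 1,
  "comment": "Bundled amino-acid property scales (one value per standard residue). A compact canonical subset; the full AAindex collection can be loaded with read_aaindex(). charge_at_ph7 and sidechain_pka are derived from the EMBOSS pKa values; heavy_atoms and residue_mass from residue composition.",
  "scales": {
    "hydropathy_kd": {
      "description": "Kyte-Doolittle hydropathy index",
      "values": {"A": 1.8, "R": -4.5, "N": -3.5, "D": -3.5, "C": 2.5, "Q": -3.5, "E": -3.5, "G": -0.4, "H": -3.2, "I": 4.5, "L": 3.8, "K": -3.9, "M": 1.9, "F": 2.8, "P": -1.6, "S": -0.8, "T": -0.7, "W": -0.9, "Y": -1.3, "V": 4.2}
    },
    "hydrophilicity_hw": {
      "description": "Hopp-Woods hydrophilicity",
      "values": {"A": -0.5, "R": 3.0, "N": 0.2, "D": 3.0, "C": -1.0, "Q": 0.2, "E": 3.0, "G": 0.0, "H": -0.5, "I": -1.8, "L": -1.8, "K": 3.0, "M": -1.3, "F": -2.5, "P": 0.0, "S": 0.3, "T": -0.4, "W": -3.4, "Y": -2.3, "V": -1.5}
    },
    "hydrophobicity_eisenberg": {
      "description": "Eisenberg consensus hydrophobicity",
      "values": {"A": 0.62, "R": -2.53, "N": -0.78, "D": -0.9, "C": 0.29, "Q": -0.85, "E": -0.74, "G": 0.48, "H": -0.4, "I": 1.38, "L": 1.06, "K": -1.5, "M": 0.64, "F": 1.19, "P": 0.12, "S": -0.18, "T": -0.05, "W": 0.81, "Y": 0.26, "V": 1.08}
    },
    "residue_mass": {
      "description": "Average residue mass, Da",
      "values": {"A": 71.0788, "R": 156.1875, "N": 114.1038, "D": 115.0886, "C": 103.1388, "Q": 128.1307, "E": 129.1155, "G": 57.0519, "H": 137.1411, "I": 113.1594, "L": 113.1594, "K": 128.1741, "M": 131.1926, "F": 147.1766, "P": 97.1167, "S": 87.0782, "T": 101.1051, "W": 186.2132, "Y": 163.176, "V": 99.1326}
    },
    "residue_volume": {
      "description": "Zamyatnin residue volume, cubic Angstrom",
      "values": {"A": 88.6, "R": 173.4, "N": 114.1, "D": 111.1, "C": 108.5, "Q": 143.8, "E": 138.4, "G": 60.1, "H": 153.2, "I": 166.7, "L": 166.7, "K": 168.6, "M": 162.9, "F": 189.9, "P": 112.7, "S": 89.0, "T": 116.1, "W": 227.8, "Y": 193.6, "V": 140.0}
    },
    "heavy_atoms": {
      "description": "Non-hydrogen atoms per residue",
      "values": {"A": 5, "R": 11, "N": 8, "D": 8, "C": 6, "Q": 9, "E": 9, "G": 4, "H": 10, "I": 8, "L": 8, "K": 9, "M": 8, "F": 11, "P": 7, "S": 6, "T": 7, "W": 14, "Y": 12, "V": 7}
    },
    "bulkiness_zimmerman": {
      "description": "Zimmerman bulkiness",
      "values": {"A": 11.5, "R": 14.28, "N": 12.82, "D": 11.68, "C": 13.46, "Q": 14.45, "E": 13.57, "G": 3.4, "H": 13.69, "I": 21.4, "L": 21.4, "K": 15.71, "M": 16.25, "F": 19.8, "P": 17.43, "S": 9.47, "T": 15.77, "W": 21.67, "Y": 18.03, "V": 21.57}
    },
    "polarity_grantham": {
      "description": "Grantham polarity",
      "values": {"A": 8.1, "R": 10.5, "N": 11.6, "D": 13.0, "C": 5.5, "Q": 10.5, "E": 12.3, "G": 9.0, "H": 10.4, "I": 5.2, "L": 4.9, "K": 11.3, "M": 5.7, "F": 5.2, "P": 8.0, "S": 9.2, "T": 8.6, "W": 5.4, "Y": 6.2, "V": 5.9}
    },
    "aa_pi": {
      "description": "Isoelectric point of the free amino acid",
      "values": {"A": 6.01, "R": 10.76, "N": 5.41, "D": 2.77, "C": 5.07, "Q": 5.65, "E": 3.22, "G": 5.97, "H": 7.59, "I": 6.02, "L": 5.98, "K": 9.74, "M": 5.74, "F": 5.48, "P": 6.48, "S": 5.68, "T": 5.87, "W": 5.89, "Y": 5.66, "V": 5.97}
    },
    "helix_chou_fasman": {
      "description": "Chou-Fasman alpha-helix propensity (Pa)",
      "values": {"A": 1.42, "R": 0.98, "N": 0.67, "D": 1.01, "C": 0.7, "Q": 1.11, "E": 1.51, "G": 0.57, "H": 1.0, "I": 1.08, "L": 1.21, "K": 1.16, "M": 1.45, "F": 1.13, "P": 0.57, "S": 0.77, "T": 0.83, "W": 1.08, "Y": 0.69, "V": 1.06}
    },
    "sheet_chou_fasman": {
      "description": "Chou-Fasman beta-sheet propensity (Pb)",
      "values": {"A": 0.83, "R": 0.93, "N": 0.89, "D": 0.54, "C": 1.19, "Q": 1.1, "E": 0.37, "G": 0.75, "H": 0.87, "I": 1.6, "L": 1.3, "K": 0.74, "M": 1.05, "F": 1.38, "P": 0.55, "S": 0.75, "T": 1.19, "W": 1.37, "Y": 1.47, "V": 1.7}
    },
    "turn_chou_fasman": {
      "description": "Chou-Fasman beta-turn propensity (Pt)",
      "values": {"A": 0.66, "R": 0.95, "N": 1.56, "D": 1.46, "C": 1.19, "Q": 0.98, "E": 0.74, "G": 1.56, "H": 0.95, "I": 0.47, "L": 0.59, "K": 1.01, "M": 0.6, "F": 0.6, "P": 1.52, "S": 1.43, "T": 0.96, "W": 0.96, "Y": 1.14, "V": 0.5}
    },
    "charge_at_ph7": {
      "description": "Expected side-chain charge at pH 7 under the EMBOSS pKa values",
      "values": {"A": 0.0, "R": 1.0, "N": 0.0, "D": -0.999, "C": -0.031, "Q": 0.0, "E": -0.999, "G": 0.0, "H": 0.24, "I": 0.0, "L": 0.0, "K": 1.0, "M": 0.0, "F": 0.0, "P": 0.0, "S": 0.0, "T": 0.0, "W": 0.0, "Y": -0.001, "V": 0.0}
    },
    "sidechain_pka": {
      "description": "EMBOSS side-chain pKa; 7.0 (neutral) for non-ionizable residues",
      "values": {"A": 7.0, "R": 12.5, "N": 7.0, "D": 3.9, "C": 8.5, "Q": 7.0, "E": 4.1, "G": 7.0, "H": 6.5, "I": 7.0, "L": 7.0, "K": 10.8, "M": 7.0, "F": 7.0, "P": 7.0, "S": 7.0, "T": 7.0, "W": 7.0, "Y": 10.1, "V": 7.0}
    },
    "aromaticity": {
      "description": "Aromatic side chain indicator (F, W, Y, H)",
      "values": {"A": 0, "R": 0, "N": 0, "D": 0, "C": 0, "Q": 0, "E": 0, "G": 0, "H": 1, "I": 0, "L": 0, "K": 0, "M": 0, "F": 1, "P": 0, "S": 0, "T": 0, "W": 1, "Y": 1, "V": 0}
    }
  }
}
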