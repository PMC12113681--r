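"""Batch SMILES helper: canonicalisation and ECFP (Morgan) fingerprints.

Usage:
    python ecfp.py canon  < smiles.txt
    python ecfp.py fp RADIUS NBITS < smiles.txt

One SMILES per input line. Output, one line per input:
    canon -> canonical SMILES, or the empty string for unparseable input
    fp    -> space-separated on-bit indices, or the literal token INVALID
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main() -> None:
    mode = sys.argv[1]
    if mode == "fp":
        radius, n_bits = int(sys.argv[2]), int(sys.argv[3])
    for line in sys.stdin:
        smi = line.rstrip("\n")
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mode == "canon":
            print(Chem.MolToSmiles(mol) if mol is not None else "")
        else:
            if mol is None:
                print("INVALID")
            else:
                fp = AllChem.GetMorganFingerprintAsBitVect(
                    mol, radius, nBits=n_bits
                )
                print(" ".join(str(b) for b in fp.GetOnBits()))


if __name__ == "__main__":
    main()
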