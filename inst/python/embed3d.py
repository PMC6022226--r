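"""Deterministic 3D embedding service for the R package.

Reads a tab-separated file of `SMILES<TAB>id` lines, embeds each molecule
(explicit hydrogens, ETKDG with the given random seed, force-field
relaxation with MMFF94 falling back to UFF) and writes a multi-record V2000
SD file.  A molecule that cannot be embedded produces a record whose title
line is `__FAILED__<TAB>id` so the caller can report per-molecule errors.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def main(infile, outfile, seed):
    out = []
    for line in open(infile):
        line = line.strip()
        if not line:
            continue
        smi, _, mid = line.partition("\t")
        mid = mid or "mol"
        block = None
        mol = Chem.MolFromSmiles(smi)
        if mol is not None:
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = int(seed)
            if AllChem.EmbedMolecule(mol, params) == 0:
                try:
                    if AllChem.MMFFHasAllMoleculeParams(mol):
                        AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
                    else:
                        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
                except Exception:
                    pass
                mol.SetProp("_Name", mid)
                block = Chem.MolToMolBlock(mol, kekulize=True)
        if block is None:
            out.append("__FAILED__\t" + mid + "\n\n\n"
                       "  0  0  0  0  0  0  0  0  0  0999 V2000\nM  END\n$$$$\n")
        else:
            out.append(block + "$$$$\n")
    with open(outfile, "w") as fh:
        fh.writelines(out)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
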