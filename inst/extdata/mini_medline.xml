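<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>100001</PMID>
      <Article>
        <Journal><Title>Clin Pharmacokinet</Title></Journal>
        <ArticleTitle>Pharmacokinetics of drug X in rats</ArticleTitle>
        <Abstract>
          <AbstractText Label="BACKGROUND">Single-dose study.</AbstractText>
          <AbstractText Label="RESULTS">Clearance was 5.2 L/h and half-life 3.1 h (dose 10 mg/kg, peak 0.8 μg/mL).</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <LastName>Smith</LastName>
            <ForeName>Jordan</ForeName>
            <AffiliationInfo><Affiliation>Institute of Pharmacy, Example University</Affiliation></AffiliationInfo>
          </Author>
        </AuthorList>
        <PublicationTypeList>
          <PublicationType>Journal Article</PublicationType>
        </PublicationTypeList>
      </Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName>Pharmacokinetics</DescriptorName><QualifierName>methods</QualifierName></MeshHeading>
        <MeshHeading><DescriptorName>Rats</DescriptorName></MeshHeading>
      </MeshHeadingList>
      <ChemicalList>
        <Chemical><NameOfSubstance>midazolam</NameOfSubstance></Chemical>
      </ChemicalList>
      <KeywordList><Keyword>clearance</Keyword></KeywordList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>100002</PMID>
      <Article>
        <Journal><Title>Drug Metab Rev</Title></Journal>
        <ArticleTitle>A review of hepatic drug metabolism</ArticleTitle>
        <PublicationTypeList>
          <PublicationType>Review</PublicationType>
        </PublicationTypeList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>100003</PMID>
      <Article>
        <ArticleTitle>Population modelling of valproic acid exposure</ArticleTitle>
        <Abstract>
          <AbstractText>Volume of distribution was estimated at 0.2 L/kg in children receiving valproic acid.</AbstractText>
        </Abstract>
        <PublicationTypeList>
          <PublicationType>Journal Article</PublicationType>
          <PublicationType>Clinical Trial</PublicationType>
        </PublicationTypeList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
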